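# Canonicalization, DeepSMILES/SELFIES codecs, tokenizer and vocabulary.

test_that("canonicalize maps spellings of one molecule to one string", {
  expect_same_molecule("OCC", "CCO")
  expect_same_molecule("c1ccccc1", "C1=CC=CC=C1")          # aromatic perception
  expect_same_molecule("c1ccc2ccccc2c1", "C1=CC2=CC=CC=C2C=C1")
  expect_same_molecule("CC(=O)OC1=CC=CC=C1C(=O)O", "CC(=O)Oc1ccccc1C(=O)O")
  can <- canonicalize("CC(C)CCO")
  expect_identical(canonicalize(can), can)                  # idempotence
  expect_error(canonicalize("not(("), class = "ocsr_parse_error")
})

test_that("canonicalization is invariant under atom re-orderings", {
  # re-spell via the DeepSMILES round trip from rotated inputs
  spellings <- list(
    c("N#Cc1ccccc1", "c1ccccc1C#N"),
    c("CC1CCC(CC1)C(C)C", "C(C)(C)C1CCC(C)CC1"),
    c("c1cc[nH]c1", "[nH]1cccc1"))
  for (pair in spellings) expect_same_molecule(pair[1], pair[2])
})

test_that("DeepSMILES encoding matches the reference conversion rules", {
  expect_identical(to_deepsmiles("CCO"), "CCO")       # no rings, no branches
  expect_identical(to_deepsmiles("c1ccccc1"), "cccccc6")
  expect_identical(to_deepsmiles("CC(C)O"), "CCC)O")
  expect_identical(to_deepsmiles("CC(C)(C)C"), "CCC)C)C")
  expect_identical(to_deepsmiles("C1CC(F)CC1"), "CCCF)CC5")
})

test_that("undecodable DeepSMILES signals invalid structure", {
  expect_error(from_deepsmiles("CC4"), class = "ocsr_invalid_structure")
  expect_error(from_deepsmiles(")CC"), class = "ocsr_invalid_structure")
  expect_error(from_deepsmiles("CC(O"), class = "ocsr_invalid_structure")
  expect_error(from_deepsmiles(""), class = "ocsr_invalid_structure")
})

test_that("SELFIES decodes the published symbol semantics", {
  expect_same_molecule(from_selfies("[C][C][O]"), "CCO")
  expect_same_molecule(from_selfies("[C][=C][C][=C][C][=C][Ring1][=Branch1]"),
                       "c1ccccc1")
  expect_error(from_selfies("[Ring1][Branch1]"),
               class = "ocsr_invalid_structure")   # no atoms derivable
})

test_that("representation round-trips preserve canonical identity", {
  mols <- small_fixture_mols()
  extra <- c("c1ccccc1", "c1ccncc1", "c1cc[nH]c1", "CC(=O)Oc1ccccc1C(=O)O",
             "FC(F)(F)c1ccccc1", "CC(C)(C)c1ccc(O)cc1")
  smis <- c(vapply(mols, `[[`, "", "canonical_smiles"), vapply(extra, canonicalize, ""))
  for (s in smis) {
    expect_identical(canonicalize(from_deepsmiles(to_deepsmiles(s))), s)
    expect_identical(canonicalize(from_selfies(to_selfies(s))), s)
  }
})

test_that("shuffled SELFIES symbol sequences still decode (robustness)", {
  base <- tokenize(to_selfies(canonicalize("CC(=O)Oc1ccccc1C(=O)O")), "selfies")
  body <- base[2:(length(base) - 1L)]
  set.seed(42)
  for (i in 1:100) {
    shuffled <- paste(sample(body), collapse = "")
    expect_silent(smi <- from_selfies(shuffled))
    expect_s3_class(parse_smiles(smi), "ocsr_mol")
  }
})

test_that("tokenizer follows the longest-match rules", {
  expect_identical(tokenize("CCO"), c("<start>", "C", "C", "O", "<end>"))
  expect_identical(tokenize("CCl"), c("<start>", "C", "Cl", "<end>"))
  expect_identical(tokenize("[C][Branch1]", "selfies"),
                   c("<start>", "[C]", "[Branch1]", "<end>"))
  expect_identical(tokenize("C%12CC%12C")[2:6], c("C", "%12", "C", "C", "%12"))
  expect_identical(tokenize("[nH]1cccc1")[2], "[nH]")
  expect_error(tokenize("C[nH"), class = "ocsr_tokenize_error")
  expect_error(tokenize("[C][C", "selfies"), class = "ocsr_tokenize_error")
})

test_that("tokenize/detokenize are mutually inverse on all representations", {
  for (rec in small_fixture_mols()[1:12]) {
    s <- rec$canonical_smiles
    for (repr in c("smiles", "deepsmiles", "selfies")) {
      text <- switch(repr, smiles = s, deepsmiles = to_deepsmiles(s),
                     selfies = to_selfies(s))
      toks <- tokenize(text, repr)
      expect_identical(detokenize(toks), text)
      expect_identical(toks[1], "<start>")
      expect_identical(toks[length(toks)], "<end>")
      expect_false(any(toks[2:(length(toks) - 1L)] %in%
                       c("<start>", "<end>", "<pad>")))
    }
  }
})

test_that("vocabulary build is deterministic and permutation-invariant", {
  corpus <- lapply(c("CCO", "CCl", "c1ccccc1"), tokenize)
  v1 <- build_vocabulary(corpus)
  v2 <- build_vocabulary(rev(corpus))
  expect_identical(v1$token_to_index, v2$token_to_index)
  # reserved tokens first, pad at zero
  expect_equal(unname(v1$token_to_index[c("<pad>", "<start>", "<end>", "<unk>")]),
               0:3)
  expect_equal(v1$size, length(unique(unlist(corpus))) + 2L)  # + pad, unk
  expect_equal(v1$max_length, max(lengths(corpus)))

  single <- build_vocabulary(list(tokenize("CCO")))
  expect_setequal(single$index_to_token,
                  c("<pad>", "<start>", "<end>", "<unk>", "C", "O"))
  expect_equal(single$size, 6L)
})

test_that("index encoding pads with zero, maps unknowns, and inverts", {
  vocab <- build_vocabulary(list(tokenize("CCO")))
  idx <- encode_indices(tokenize("CO"), vocab, max_length = 6L)
  expect_length(idx, 6L)
  expect_equal(idx[1], 1L)                         # <start>
  expect_equal(idx[5:6], c(0L, 0L))                # padding
  expect_identical(decode_indices(idx, vocab), tokenize("CO"))

  unk <- encode_indices(c("<start>", "N", "<end>"), vocab)
  expect_equal(unk[2], unname(vocab$token_to_index[["<unk>"]]))

  expect_error(encode_indices(tokenize("CCCCCCCO"), vocab),
               class = "ocsr_length_overflow")
})

test_that("vocabulary JSON round-trips", {
  vocab <- build_vocabulary(lapply(c("CCO", "CCl"), tokenize))
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(vocab, path)
  back <- read_vocabulary(path)
  expect_identical(back$index_to_token, vocab$index_to_token)
  expect_identical(back$max_length, vocab$max_length)
})
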