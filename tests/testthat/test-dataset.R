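# Fixture generation, dataset packaging, split hygiene and batch streaming.

test_that("fixture generation is deterministic, clean and collision-free", {
  a <- generate_fixtures(fixture_config(30, seed = 7))
  b <- generate_fixtures(fixture_config(30, seed = 7))
  sa <- vapply(a, `[[`, "", "canonical_smiles")
  expect_identical(sa, vapply(b, `[[`, "", "canonical_smiles"))
  expect_equal(anyDuplicated(sa), 0L)
  for (rec in a) expect_length(check_rules(rec), 0L)

  c_ <- generate_fixtures(fixture_config(30, seed = 8))
  expect_false(identical(sa, vapply(c_, `[[`, "", "canonical_smiles")))
})

test_that("packaging splits records and persists a reloadable manifest", {
  mols <- generate_fixtures(fixture_config(20, seed = 31))
  dir <- withr::local_tempdir()
  ds <- package_dataset(mols, "smiles", dir, base_seed = 9,
                        test_fraction = 0.1, canvas_px = 96L)
  expect_equal(sum(ds$split == "test"), 2L)
  expect_equal(sum(ds$split == "train"), 18L)
  # disjoint and exhaustive by construction
  expect_setequal(c(dataset_split(ds, "train"), dataset_split(ds, "test")),
                  ds$records)

  # every target starts with <start> and has exactly one <end> before pads
  for (r in ds$records) {
    expect_equal(r$target[1], 1L)
    ends <- which(r$target == 2L)
    expect_length(ends, 1L)
    if (ends < length(r$target)) {
      expect_true(all(r$target[(ends + 1L):length(r$target)] == 0L))
    }
  }

  reload <- load_dataset(dir)
  expect_identical(lapply(reload$records, `[[`, "target"),
                   lapply(ds$records, `[[`, "target"))
  expect_identical(reload$vocab$index_to_token, ds$vocab$index_to_token)
})

test_that("vocabulary derives from the train split only; UNK guards the rest", {
  mols <- generate_fixtures(fixture_config(15, seed = 55))
  dir <- withr::local_tempdir()
  ds <- package_dataset(mols, "deepsmiles", dir, base_seed = 2,
                        test_fraction = 0.2, canvas_px = 96L)
  train_tokens <- unique(unlist(lapply(dataset_split(ds, "train"),
    function(r) tokenize(r$text, "deepsmiles"))))
  expect_true(all(train_tokens %in% ds$vocab$index_to_token))
  unk <- unname(ds$vocab$token_to_index[["<unk>"]])
  for (r in dataset_split(ds, "test")) {
    toks <- tokenize(r$text, "deepsmiles")
    enc <- encode_indices(toks, ds$vocab, ds$pad_length)
    known <- toks %in% ds$vocab$index_to_token
    expect_true(all(enc[which(!known)] == unk))
  }
})

test_that("re-packaging with the same seeds is byte-identical", {
  mols <- generate_fixtures(fixture_config(8, seed = 13))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- package_dataset(mols, "smiles", d1, base_seed = 21, canvas_px = 96L)
  ds2 <- package_dataset(mols, "smiles", d2, base_seed = 21, canvas_px = 96L)
  expect_identical(ds1$split, ds2$split)
  expect_identical(lapply(ds1$records, `[[`, "target"),
                   lapply(ds2$records, `[[`, "target"))
  for (i in seq_along(ds1$records)) {
    expect_identical(
      readBin(ds1$records[[i]]$image_path, "raw",
              file.size(ds1$records[[i]]$image_path)),
      readBin(ds2$records[[i]]$image_path, "raw",
              file.size(ds2$records[[i]]$image_path)))
  }
})

test_that("batches partition each epoch exactly once, short tail included", {
  samples <- lapply(1:90, function(i) list(
    features = matrix(i, 2L, 3L), target = c(1L, 2L, 0L), molecule_id = i))
  bs <- batches(samples, 32L, shuffle_seed = 3L, epoch = 1L)
  expect_equal(vapply(bs, function(b) nrow(b$targets), 0L), c(32L, 32L, 26L))
  seen <- unlist(lapply(bs, `[[`, "idx"))
  expect_setequal(seen, 1:90)
  expect_length(seen, 90L)

  # deterministic per (epoch, seed); epoch-salted
  bs2 <- batches(samples, 32L, shuffle_seed = 3L, epoch = 1L)
  expect_identical(lapply(bs, `[[`, "idx"), lapply(bs2, `[[`, "idx"))
  bs3 <- batches(samples, 32L, shuffle_seed = 3L, epoch = 2L)
  expect_false(identical(unlist(lapply(bs, `[[`, "idx")),
                         unlist(lapply(bs3, `[[`, "idx"))))
})
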