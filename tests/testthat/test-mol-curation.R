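# Molecule parsing, record fields and the curation rules.

test_that("benzene record matches the independent hand tally", {
  # hand tally of the benzene graph: 6 ring edges; 6 C (12.011) + 6 H (1.008)
  rec <- molecule_record("c1ccccc1")
  expect_equal(rec$bond_count, 6L)
  expect_equal(rec$mol_weight, 6 * 12.011 + 6 * 1.008, tolerance = 1e-9)
  expect_equal(rec$fragment_count, 1L)
  expect_equal(nchar(rec$canonical_smiles), 8L)
  expect_length(check_rules(rec), 0L)
})

test_that("molecule record invariants hold on generated molecules", {
  for (rec in small_fixture_mols()[1:15]) {
    expect_same_molecule(rec$canonical_smiles, rec$mol$smiles)
    expect_gt(rec$mol_weight, 0)
    expect_gte(rec$fragment_count, 1L)
  }
})

test_that("each rule is detected and attributed correctly", {
  expect_setequal(check_rules("[Na+].[Cl-]"),
                  c("R2_counter_ions", "R3_elements", "R6_charges",
                    "R5_bond_count"))
  expect_true("R5_bond_count" %in% check_rules("CC"))        # 1 bond < 5
  expect_true("R4_isotopes" %in% check_rules("[2H]OCCCCC"))  # deuterium
  expect_true("R7_explicit_hydrogen" %in% check_rules("[H]OCCCCC"))
  expect_true("R6_charges" %in% check_rules("[NH3+]CCCCC"))
  # R1: a long perfluorinated chain tops 1500 Da within 40 bonds
  heavy <- paste0("C(I)(I)", strrep("C(I)(I)", 11))
  rec <- molecule_record(heavy)
  expect_gt(rec$mol_weight, 1500)
  expect_true("R1_mol_weight" %in% check_rules(rec))
  # R8: >= 40 canonical SMILES characters but still <= 40 bonds
  long <- paste0(strrep("C(Br)", 10), "C")  # 20 bonds, ~51 characters
  expect_lte(molecule_record(long)$bond_count, 40L)
  expect_true("R8_smiles_length" %in% check_rules(long))
  # R3 alone
  expect_true("R3_elements" %in% check_rules("CCCCC[Si](C)(C)C"))
})

test_that("bracket implicit hydrogens are allowed, explicit H nodes are not", {
  expect_false("R7_explicit_hydrogen" %in% check_rules("c1cc[nH]c1CC"))
  expect_true("R7_explicit_hydrogen" %in% check_rules("[H]C([H])CCCC"))
})

test_that("curate_stream partitions, counts, and preserves order", {
  out <- curate_stream(c("c1ccccc1", "CC"))
  expect_equal(out$report$n_input, 2L)
  expect_equal(out$report$n_accepted, 1L)
  expect_equal(unname(out$report$rejections[["R5_bond_count"]]), 1L)
  expect_equal(out$accepted[[1]]$canonical_smiles, canonicalize("c1ccccc1"))

  empty <- curate_stream(character(0))
  expect_equal(empty$report$n_input, 0L)
  expect_equal(empty$report$n_accepted, 0L)
  expect_length(empty$accepted, 0L)

  # parse failures counted separately, never abort the stream
  mixed <- curate_stream(c("c1ccccc1", "not-a-smiles((", "CCCCCO"))
  expect_equal(mixed$report$n_parse_failures, 1L)
  expect_equal(mixed$report$n_accepted, 2L)
})

test_that("curation is idempotent and rejection counts are consistent", {
  mols <- small_fixture_mols()
  smis <- vapply(mols, `[[`, "", "canonical_smiles")
  first <- curate_stream(smis)
  expect_equal(first$report$n_accepted, length(smis))
  again <- curate_stream(vapply(first$accepted, `[[`, "", "canonical_smiles"))
  expect_equal(again$report$n_accepted, length(smis))

  # every accepted molecule re-checks clean, rule by rule
  for (rec in first$accepted[1:10]) expect_length(check_rules(rec), 0L)

  # sum of causes >= rejected count (multi-violations increment several)
  bad <- curate_stream(c("[Na+].[Cl-]", "CC", "c1ccccc1"))
  n_rej <- bad$report$n_input - bad$report$n_accepted -
    bad$report$n_parse_failures
  expect_gte(sum(bad$report$rejections), n_rej)
})

test_that("SMILES file IO round-trips ids and handles comments", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header comment", "m1\tc1ccccc1", "", "CCO"), path)
  df <- read_smiles_file(path)
  expect_equal(nrow(df), 2L)
  expect_equal(df$id[1], "m1")
  expect_match(df$id[2], "^mol")

  cur <- curate_stream(df)
  out_tsv <- withr::local_tempfile(fileext = ".tsv")
  out_json <- withr::local_tempfile(fileext = ".json")
  write_curation(cur, out_tsv, out_json)
  rep <- jsonlite::read_json(out_json)
  expect_equal(rep$n_input, 2L)
  expect_named(rep$rejections)
})
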