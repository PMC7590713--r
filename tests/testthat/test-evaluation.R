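# Fingerprints, Tanimoto, evaluation reports, histogram, descriptors,
# extrapolation.

brute_tanimoto <- function(a, b) {
  # independent bit-set oracle: explicit set arithmetic on bit positions
  sa <- which(as.logical(a)); sb <- which(as.logical(b))
  length(intersect(sa, sb)) / length(union(sa, sb))
}

test_that("fingerprints are canonical-identity functions of the molecule", {
  f1 <- fingerprint("OCC")
  f2 <- fingerprint("CCO")
  expect_identical(unclass(f1)[], unclass(f2)[])
  expect_false(identical(which(as.logical(fingerprint("c1ccccc1"))),
                         which(as.logical(fingerprint("CCO")))))
  expect_length(f1, 881L)
  expect_equal(attr(f1, "popcount"), sum(f1))
  # every >= 2-atom molecule fires at least one key
  for (rec in small_fixture_mols()[1:10]) {
    expect_gt(attr(fingerprint(rec), "popcount"), 0L)
  }
})

test_that("tanimoto agrees exactly with the brute-force oracle", {
  # spec'd closed cases
  f <- fingerprint("CCCCO")
  expect_equal(tanimoto(f, f), 1.0)
  a <- structure(c(TRUE, TRUE, TRUE, FALSE, FALSE), popcount = 3L)
  b <- structure(c(FALSE, TRUE, TRUE, TRUE, FALSE), popcount = 3L)
  expect_equal(tanimoto(a, b), 0.5)                       # {1,2,3} vs {2,3,4}
  disj <- structure(c(FALSE, FALSE, FALSE, TRUE, TRUE), popcount = 2L)
  expect_equal(tanimoto(a, disj), 0.0)
  expect_error(tanimoto(a, b[-1]), class = "ocsr_contract_violation")
  zero <- structure(rep(FALSE, 5), popcount = 0L)
  expect_error(tanimoto(zero, zero), class = "ocsr_undefined_similarity")

  set.seed(17)
  for (i in 1:1000) {
    x <- runif(64) < 0.3
    y <- runif(64) < 0.3
    if (!any(x | y)) next
    expect_identical(tanimoto(x, y), brute_tanimoto(x, y))
  }
})

test_that("evaluate handles the identity and the all-invalid cases", {
  mols <- vapply(small_fixture_mols()[1:6], `[[`, "", "canonical_smiles")
  rep1 <- evaluate(data.frame(reference = mols, predicted = mols), "smiles")
  expect_equal(rep1$valid_pct, 100)
  expect_equal(rep1$avg_tanimoto, 1.0)
  expect_equal(rep1$tanimoto1_pct, 100)

  rep2 <- evaluate(data.frame(reference = mols,
                              predicted = rep("((((", 6L)), "smiles")
  expect_equal(rep2$invalid_pct, 100)
  expect_true(is.na(rep2$avg_tanimoto))          # not-a-value, not 0
  expect_equal(rep2$tanimoto1_pct, 0)
  expect_null(rep2$histogram)

  expect_error(evaluate(data.frame(reference = "((bad((", predicted = "CCO"),
                        "smiles"), class = "ocsr_invalid_reference")
})

test_that("the constructed four-outcome example reproduces the arithmetic", {
  # CCCCCO vs CCCCCN have Tanimoto exactly 1/2 under this fingerprint
  # (verified by the brute-force oracle below); 2 exact + 1 invalid +
  # 1 half-similar gives valid 75%, tanimoto1 50%, avg (1+1+0.5)/3
  expect_equal(brute_tanimoto(fingerprint("CCCCCO"), fingerprint("CCCCCN")), 0.5)
  rep <- evaluate(data.frame(
    reference = c("CCCCCO", "c1ccccc1", "CCCCCO", "CCCCCC"),
    predicted = c("CCCCCO", "c1ccccc1", "CCC((", "CCCC=CC")), "smiles")
  expect_equal(rep$valid_pct, 75)
  expect_equal(rep$tanimoto1_pct, 50)
  expect_equal(rep$avg_tanimoto, (1 + 1 + 0.5) / 3, tolerance = 1e-9)
})

test_that("representation decoding failures count as invalid predictions", {
  refs <- vapply(c("CCCCCO", "CCCCCC"), to_deepsmiles, "")
  rep <- evaluate(data.frame(reference = refs,
                             predicted = c(refs[1], "CC9")), "deepsmiles")
  expect_equal(rep$valid_pct, 50)
  sf <- to_selfies("CCCCCO")
  rep2 <- evaluate(data.frame(reference = sf, predicted = sf), "selfies")
  expect_equal(rep2$avg_tanimoto, 1.0)
})

test_that("histogram bins correctly and always sums to 100", {
  h <- tanimoto_histogram(c(0.05, 0.55, 1.0))
  expect_equal(h$percentage[h$bin == "[0.0,0.1)"], 100 / 3, tolerance = 1e-9)
  expect_equal(h$percentage[h$bin == "[0.5,0.6)"], 100 / 3, tolerance = 1e-9)
  expect_equal(h$percentage[h$bin == "1.0"], 100 / 3, tolerance = 1e-9)
  expect_equal(sum(h$percentage), 100, tolerance = 1e-9)

  all1 <- tanimoto_histogram(rep(1, 5))
  expect_equal(all1$percentage[11], 100)
  expect_equal(sum(all1$percentage[1:10]), 0)

  expect_error(tanimoto_histogram(numeric(0)), class = "ocsr_empty_histogram")

  set.seed(5)
  for (i in 1:50) {
    x <- runif(sample(1:40, 1))
    expect_equal(sum(tanimoto_histogram(x)$percentage), 100, tolerance = 1e-9)
  }
})

test_that("valid + invalid percentages always sum to 100 (property)", {
  pool_ok <- c("CCCCCO", "CCCCCC", "c1ccccc1", "CCCCN")
  pool_bad <- c("((", "C1CC", "xx")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    preds <- sample(c(pool_ok, pool_bad), n, replace = TRUE)
    refs <- sample(pool_ok, n, replace = TRUE)
    rep <- evaluate(data.frame(reference = refs, predicted = preds), "smiles")
    expect_equal(rep$valid_pct + rep$invalid_pct, 100, tolerance = 1e-9)
    if (!is.null(rep$histogram)) {
      expect_equal(sum(rep$histogram$percentage), 100, tolerance = 1e-9)
    }
    expect_lte(rep$tanimoto1_pct, rep$valid_pct + 1e-9)
  }
})

test_that("evaluate is permutation-invariant and monotone in fixes", {
  refs <- c("CCCCCO", "CCCCCC", "c1ccccc1", "CCCCN")
  preds <- c("CCCCCO", "((", "c1ccccc1", "CCCCCC")
  r1 <- evaluate(data.frame(reference = refs, predicted = preds), "smiles")
  perm <- c(3L, 1L, 4L, 2L)
  r2 <- evaluate(data.frame(reference = refs[perm], predicted = preds[perm]),
                 "smiles")
  expect_equal(r1$avg_tanimoto, r2$avg_tanimoto)
  expect_equal(r1$valid_pct, r2$valid_pct)

  # replace the invalid prediction by an exact one: all three stats rise
  fixed <- preds; fixed[2] <- refs[2]
  r3 <- evaluate(data.frame(reference = refs, predicted = fixed), "smiles")
  expect_gte(r3$valid_pct, r1$valid_pct)
  expect_gte(r3$tanimoto1_pct, r1$tanimoto1_pct)
  expect_gte(r3$avg_tanimoto, r1$avg_tanimoto)
})

test_that("descriptor deltas are zero on identity and count rings", {
  expect_equal(logp_estimate("CCO"), logp_estimate("OCC"), tolerance = 1e-12)
  expect_equal(abs(ring_count(parse_smiles("c1ccccc1")) -
                   ring_count(parse_smiles("CCO"))), 1L)
  mols <- vapply(small_fixture_mols()[1:5], `[[`, "", "canonical_smiles")
  rep <- evaluate(data.frame(reference = mols, predicted = mols), "smiles")
  expect_equal(rep$descriptor_deltas$mean_abs_dlogp, 0)
  expect_equal(rep$descriptor_deltas$mean_abs_dring, 0)
  rep2 <- evaluate(data.frame(reference = "c1ccccc1C", predicted = "CCCCCO"),
                   "smiles")
  expect_equal(rep2$descriptor_deltas$mean_abs_dring, 1)
  expect_gte(rep2$descriptor_deltas$mean_abs_dlogp, 0)
})

test_that("linear extrapolation recovers exact lines and refuses flat ones", {
  fit <- linear_extrapolate(data.frame(size = c(1, 2), accuracy = c(10, 20)), 100)
  expect_equal(fit$required_size, 10, tolerance = 1e-9)

  pts <- data.frame(size = c(1e6, 2e6, 3e6), accuracy = c(10, 30, 50))
  fit2 <- linear_extrapolate(pts, 90)
  expect_equal(fit2$slope, 2e-5, tolerance = 1e-12)
  expect_equal(fit2$intercept, -10, tolerance = 1e-6)
  expect_equal(fit2$required_size, 5e6, tolerance = 1e-6)
  # collinear: zero residuals
  expect_equal(unname(fit2$intercept + fit2$slope * pts$size), pts$accuracy,
               tolerance = 1e-9)

  expect_error(linear_extrapolate(
    data.frame(size = c(1, 2, 3), accuracy = c(30, 20, 10)), 90),
    class = "ocsr_non_extrapolable")
  expect_error(linear_extrapolate(
    data.frame(size = c(5, 5), accuracy = c(1, 2)), 90),
    class = "ocsr_non_extrapolable")
})

test_that("prediction TSV files evaluate and malformed rows are named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("m1\tCCCCCO\tCCCCCO", "m2\tCCCCCC\t(("), path)
  rep <- evaluate_file(path, "smiles")
  expect_equal(rep$n, 2L)
  expect_equal(rep$valid_pct, 50)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("m1\tCCCCCO\tCCCCCO", "m2-missing-field"), bad)
  err <- tryCatch(evaluate_file(bad, "smiles"), ocsr_usage_error = function(e) e)
  expect_s3_class(err, "ocsr_usage_error")
  expect_match(conditionMessage(err), "line 2")

  out_json <- withr::local_tempfile(fileext = ".json")
  out_csv <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, out_json, out_csv)
  parsed <- jsonlite::read_json(out_json)
  expect_equal(parsed$valid_pct, 50)
  expect_equal(nrow(utils::read.csv(out_csv)), 11L)
})
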