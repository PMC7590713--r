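# Evaluation of predicted structure strings: substructure-key fingerprints,
# Tanimoto statistics, similarity histogram, descriptor deltas and the
# training-size extrapolation.
#
# The fingerprint is an 881-bit substructure-key scheme in the PubChem
# style: a fixed layout of element-count keys, ring keys, bond keys and
# hashed linear-path keys. The exact key definitions are this package's
# own (the published key list is external to the method); what matters for
# the Tanimoto indicators is that both sides of every comparison use the
# same scheme and that degeneracy is low.

.ocsr_fp_bits <- 881L

#' Compute the 881-bit substructure-key fingerprint of a molecule
#'
#' @param mol an `ocsr_mol`, `ocsr_molrec`, or SMILES string
#' @return object of class `ocsr_fingerprint`: logical vector of length 881
#'   with attribute `popcount`
#' @export
fingerprint <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (inherits(mol, "ocsr_molrec")) mol <- mol$mol
  stopifnot(inherits(mol, "ocsr_mol"))
  bits <- rep(FALSE, .ocsr_fp_bits)
  atoms <- mol$atoms; bonds <- mol$bonds
  thresholds <- c(1L, 2L, 4L, 8L, 16L, 32L)

  # keys 1..78: element counts at thresholds (13 x 6), H from implicit counts
  elems <- c("C", "H", "O", "N", "P", "S", "F", "Cl", "Br", "I", "Se", "B", "*")
  counts <- c(table(factor(atoms$element, levels = elems)))
  counts["H"] <- counts["H"] + sum(atoms$hcount)
  for (ei in seq_along(elems)) {
    for (ti in seq_along(thresholds)) {
      if (counts[ei] >= thresholds[ti]) bits[(ei - 1L) * 6L + ti] <- TRUE
    }
  }
  off <- 78L

  # keys 79..110: ring features
  rings <- .find_rings(mol, max_size = 12L)
  nring <- ring_count(mol)
  for (ti in seq_along(thresholds)) if (nring >= thresholds[ti]) bits[off + ti] <- TRUE
  sizes <- unique(lengths(rings))
  for (sz in sizes) if (sz >= 3L && sz <= 12L) bits[off + 6L + sz - 2L] <- TRUE
  n_arom <- sum(vapply(rings, function(r) all(atoms$aromatic[r]), FALSE))
  for (ti in seq_along(thresholds)) if (n_arom >= thresholds[ti]) bits[off + 17L + ti] <- TRUE
  hetero_ring <- any(vapply(rings, function(r) any(atoms$element[r] != "C"), FALSE))
  if (hetero_ring) bits[off + 24L] <- TRUE
  off <- 110L

  # keys 111..140: bond-order counts
  ords <- list(double = sum(bonds$order == 2L & !bonds$aromatic),
               triple = sum(bonds$order == 3L),
               aromatic = sum(bonds$aromatic))
  k <- 0L
  for (nm in names(ords)) {
    for (ti in seq_along(thresholds)) {
      k <- k + 1L
      if (ords[[nm]] >= thresholds[ti]) bits[off + k] <- TRUE
    }
  }
  off <- 140L

  # keys 141..881: hashed linear paths of 2..6 atoms (element + bond-order
  # strings, direction-canonicalized), order-independent by construction
  nhash <- .ocsr_fp_bits - off
  adj <- .adjacency(mol)
  bsym <- ifelse(bonds$aromatic, "a", as.character(bonds$order))
  paths <- new.env(parent = emptyenv())
  walk <- function(path_atoms, path_str) {
    v <- path_atoms[length(path_atoms)]
    if (length(path_atoms) >= 2L) {
      rev_str <- .reverse_path_string(path_str)
      key <- if (path_str <= rev_str) path_str else rev_str
      assign(key, TRUE, envir = paths)
    }
    if (length(path_atoms) == 6L) return()
    for (j in seq_along(adj[[v]]$nbr)) {
      w <- adj[[v]]$nbr[j]
      if (w %in% path_atoms) next
      walk(c(path_atoms, w),
           paste0(path_str, bsym[adj[[v]]$bond[j]], .fp_atom_label(atoms, w)))
    }
  }
  for (i in seq_len(nrow(atoms))) walk(i, .fp_atom_label(atoms, i))
  for (key in ls(paths)) {
    h <- 0
    for (b in utf8ToInt(key)) h <- (h * 131 + b) %% nhash
    bits[off + h + 1L] <- TRUE
  }

  structure(bits, popcount = sum(bits), class = "ocsr_fingerprint")
}

.fp_atom_label <- function(atoms, i) {
  paste0(atoms$element[i], if (atoms$aromatic[i]) "'" else "")
}

# reverse an alternating atom/bond path string, e.g. "C1O2N" -> "N2O1C"
.reverse_path_string <- function(s) {
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?'?|[123a]", s))[[1]]
  paste(rev(toks), collapse = "")
}

#' @export
print.ocsr_fingerprint <- function(x, ...) {
  cat(sprintf("<ocsr_fingerprint> %d/%d bits set\n",
              attr(x, "popcount"), length(x)))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' T = |A intersect B| / |A union B|.
#'
#' @param a,b `ocsr_fingerprint` objects (or logical vectors) of equal length
#' @return similarity in [0, 1]
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop(ocsr_condition("ocsr_contract_violation",
    "fingerprint lengths differ"))
  uni <- sum(a | b)
  if (uni == 0L) stop(ocsr_condition("ocsr_undefined_similarity",
    "Tanimoto undefined: both fingerprints empty"))
  sum(a & b) / uni
}

# decode a predicted string in the given representation to a parsed molecule,
# or NULL when invalid
.decode_prediction <- function(text, representation) {
  smi <- tryCatch(switch(representation,
    smiles = text,
    deepsmiles = from_deepsmiles(text),
    selfies = from_selfies(text)
  ), ocsr_error = function(e) NULL)
  if (is.null(smi)) return(NULL)
  tryCatch(parse_smiles(smi), ocsr_error = function(e) NULL)
}

#' Score predicted structure strings against references
#'
#' Predictions are first decoded from their representation to SMILES
#' (DeepSMILES/SELFIES decode failure means invalid), then parsed; valid
#' predictions are compared to their reference by Tanimoto similarity of the
#' substructure-key fingerprints. `avg_tanimoto` averages over VALID
#' predictions only; `tanimoto1_pct` is a percentage of ALL predictions.
#' When no prediction is valid, `avg_tanimoto` is NA (not 0).
#'
#' @param pairs data.frame with columns `reference` and `predicted` (strings
#'   in `representation`), or a list of 2-element character vectors
#' @param representation "smiles", "deepsmiles" or "selfies"
#' @return object of class `ocsr_eval_report`: n, valid_pct, invalid_pct,
#'   avg_tanimoto, tanimoto1_pct, tanimoto (per-outcome, NA when invalid),
#'   histogram, descriptor_deltas
#' @export
evaluate <- function(pairs, representation = c("smiles", "deepsmiles", "selfies")) {
  representation <- match.arg(representation)
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- data.frame(reference = vapply(pairs, `[`, "", 1L),
                        predicted = vapply(pairs, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  }
  n <- nrow(pairs)
  stopifnot(n >= 1L)
  tan <- rep(NA_real_, n)
  dlogp <- rep(NA_real_, n)
  dring <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ref_mol <- tryCatch(
      parse_smiles(switch(representation,
        smiles = pairs$reference[i],
        deepsmiles = from_deepsmiles(pairs$reference[i]),
        selfies = from_selfies(pairs$reference[i]))),
      ocsr_error = function(e) stop(ocsr_condition("ocsr_invalid_reference",
        sprintf("reference %d is not a valid %s string: %s",
                i, representation, pairs$reference[i]))))
    pred_mol <- .decode_prediction(pairs$predicted[i], representation)
    if (is.null(pred_mol)) next
    tan[i] <- tanimoto(fingerprint(ref_mol), fingerprint(pred_mol))
    dlogp[i] <- abs(logp_estimate(ref_mol) - logp_estimate(pred_mol))
    dring[i] <- abs(ring_count(ref_mol) - ring_count(pred_mol))
  }
  valid <- !is.na(tan)
  structure(list(
    n = n,
    representation = representation,
    valid_pct = 100 * mean(valid),
    invalid_pct = 100 * mean(!valid),
    avg_tanimoto = if (any(valid)) mean(tan[valid]) else NA_real_,
    tanimoto1_pct = 100 * sum(valid & tan == 1) / n,
    tanimoto = tan,
    descriptor_deltas = list(
      mean_abs_dlogp = if (any(valid)) mean(dlogp[valid]) else NA_real_,
      mean_abs_dring = if (any(valid)) mean(dring[valid]) else NA_real_),
    histogram = if (any(valid)) tanimoto_histogram(tan[valid]) else NULL
  ), class = "ocsr_eval_report")
}

#' Tanimoto similarity histogram
#'
#' Eleven bins: \[0,0.1), ..., \[0.9,1.0), and exactly 1.0. Percentages are
#' over the supplied (valid) scores and sum to 100.
#'
#' @param x an `ocsr_eval_report` or a numeric vector of Tanimoto scores
#' @return data.frame with columns `bin` and `percentage`
#' @export
tanimoto_histogram <- function(x) {
  if (inherits(x, "ocsr_eval_report")) x <- x$tanimoto[!is.na(x$tanimoto)]
  if (!length(x)) stop(ocsr_condition("ocsr_empty_histogram",
    "no valid outcomes to bin"))
  labels <- c(sprintf("[%.1f,%.1f)", seq(0, 0.9, 0.1), seq(0.1, 1, 0.1)), "1.0")
  idx <- ifelse(x == 1, 11L, pmin(floor(x * 10), 9) + 1L)
  pct <- 100 * tabulate(idx, nbins = 11L) / length(x)
  data.frame(bin = labels, percentage = pct, stringsAsFactors = FALSE)
}

#' @export
print.ocsr_eval_report <- function(x, ...) {
  cat(sprintf("<evaluation report> n=%d (%s)\n", x$n, x$representation))
  cat(sprintf("  valid: %.1f%%  invalid: %.1f%%\n", x$valid_pct, x$invalid_pct))
  cat(sprintf("  avg Tanimoto (valid): %s   Tanimoto 1.0: %.1f%%\n",
              ifelse(is.na(x$avg_tanimoto), "NA", sprintf("%.4f", x$avg_tanimoto)),
              x$tanimoto1_pct))
  cat(sprintf("  mean |dlogP|: %s   mean |dring|: %s\n",
              format(x$descriptor_deltas$mean_abs_dlogp, digits = 3),
              format(x$descriptor_deltas$mean_abs_dring, digits = 3)))
  invisible(x)
}

#' Atom-contribution logP estimate
#'
#' A coarse octanol/water partition estimate: each heavy atom contributes a
#' fixed increment by element and aromaticity, implicit hydrogens contribute
#' a per-H increment. Deterministic; intended for descriptor DELTAS between
#' reference and prediction, not absolute accuracy.
#'
#' @param mol an `ocsr_mol` or SMILES string
#' @return numeric logP estimate
#' @export
logp_estimate <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  if (inherits(mol, "ocsr_molrec")) mol <- mol$mol
  contrib <- c(C = 0.14, N = -0.60, O = -0.40, P = -0.45, S = 0.40,
               F = 0.22, Cl = 0.65, Br = 0.86, I = 1.10, Se = 0.45,
               B = 0.18, H = 0.12)
  tot <- 0
  for (i in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[i]
    base <- if (el %in% names(contrib)) contrib[[el]] else 0
    if (mol$atoms$aromatic[i] && el == "C") base <- base + 0.16
    tot <- tot + base + mol$atoms$hcount[i] * contrib[["H"]]
  }
  tot
}

#' Linear extrapolation of accuracy versus training-set size
#'
#' Ordinary least squares of accuracy (percent) on training size; the
#' required size for a target accuracy is read off the fitted line. An
#' idealistic indicator of the order of magnitude of data needed; the true
#' curve must eventually saturate.
#'
#' @param points data.frame with columns `size` and `accuracy` (>= 2 rows,
#'   non-constant size)
#' @param target_accuracy_pct target accuracy in percent
#' @return list with `slope`, `intercept`, `required_size`
#' @export
linear_extrapolate <- function(points, target_accuracy_pct) {
  stopifnot(nrow(points) >= 2L)
  if (length(unique(points$size)) < 2L) stop(ocsr_condition(
    "ocsr_non_extrapolable", "training sizes are constant"))
  fit <- stats::lm(accuracy ~ size, data = points)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop(ocsr_condition("ocsr_non_extrapolable",
    sprintf("non-positive slope %.4g: accuracy does not grow with data", slope)))
  list(slope = slope, intercept = intercept,
       required_size = (target_accuracy_pct - intercept) / slope)
}

#' Read a predictions TSV and evaluate it
#'
#' Expected columns: `molecule_id<TAB>reference<TAB>predicted`.
#'
#' @param path TSV path
#' @param representation representation of both columns
#' @return an `ocsr_eval_report`
#' @export
evaluate_file <- function(path, representation = c("smiles", "deepsmiles", "selfies")) {
  representation <- match.arg(representation)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop(ocsr_condition("ocsr_usage_error",
    sprintf("malformed predictions row at line %d of %s", bad[1], path)))
  evaluate(data.frame(
    reference = vapply(parts, `[`, "", 2L),
    predicted = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE), representation)
}

#' Serialize an evaluation report to JSON (and optionally the histogram CSV)
#' @param report an `ocsr_eval_report`
#' @param json_path output JSON path
#' @param histogram_csv optional CSV path (columns bin, percentage)
#' @return invisibly, the report
#' @export
write_eval_report <- function(report, json_path, histogram_csv = NULL) {
  jsonlite::write_json(list(
    n = report$n, representation = report$representation,
    valid_pct = report$valid_pct, invalid_pct = report$invalid_pct,
    avg_tanimoto = report$avg_tanimoto, tanimoto1_pct = report$tanimoto1_pct,
    descriptor_deltas = report$descriptor_deltas,
    histogram = report$histogram
  ), json_path, auto_unbox = TRUE, pretty = TRUE, na = "null", digits = NA)
  if (!is.null(histogram_csv) && !is.null(report$histogram)) {
    utils::write.csv(report$histogram, histogram_csv, row.names = FALSE)
  }
  invisible(report)
}
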