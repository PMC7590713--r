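# Corpus curation: the structural filter rules applied to candidate
# molecules before they enter a training corpus.
#
# R1  molecular weight < 1500 Da
# R2  single fragment (no counter ions)
# R3  elements restricted to C H O N P S F Cl Br I Se B
# R4  no isotope labels (covers D/T)
# R5  5..40 bonds
# R6  no formally charged atoms
# R7  no explicit hydrogen atoms as graph nodes (implicit-H convention)
# R8  canonical SMILES shorter than 40 characters

.ocsr_rules <- c("R1_mol_weight", "R2_counter_ions", "R3_elements",
                 "R4_isotopes", "R5_bond_count", "R6_charges",
                 "R7_explicit_hydrogen", "R8_smiles_length")

#' Build a MoleculeRecord from a structure string
#'
#' @param smiles SMILES string
#' @param id optional identifier (defaults to the canonical SMILES)
#' @return a list of class `ocsr_molrec` with fields `id`, `mol`,
#'   `canonical_smiles`, `mol_weight`, `bond_count`, `fragment_count`
#' @export
molecule_record <- function(smiles, id = NULL) {
  mol <- parse_smiles(smiles)
  can <- mol_to_smiles(mol)
  structure(list(
    id = if (is.null(id)) can else as.character(id),
    mol = mol,
    canonical_smiles = can,
    mol_weight = mol_weight(mol),
    bond_count = bond_count(mol),
    fragment_count = fragment_count(mol)
  ), class = "ocsr_molrec")
}

#' @export
print.ocsr_molrec <- function(x, ...) {
  cat(sprintf("<ocsr_molrec> %s  MW %.2f  %d bonds  %d fragment(s)\n",
              x$canonical_smiles, x$mol_weight, x$bond_count, x$fragment_count))
  invisible(x)
}

#' Check the curation rules for one molecule
#'
#' @param rec an `ocsr_molrec` (from [molecule_record()]) or a SMILES string
#' @return character vector of violated rule names (empty when clean)
#' @examples
#' check_rules("c1ccccc1")       # character(0)
#' check_rules("[Na+].[Cl-]")    # R2, R3, R6 (and R5)
#' @export
check_rules <- function(rec) {
  if (is.character(rec)) rec <- molecule_record(rec)
  stopifnot(inherits(rec, "ocsr_molrec"))
  mol <- rec$mol
  v <- character(0)
  if (!(rec$mol_weight < 1500)) v <- c(v, "R1_mol_weight")
  if (rec$fragment_count != 1L) v <- c(v, "R2_counter_ions")
  if (!all(mol$atoms$element %in% .ocsr_allowed_elements))
    v <- c(v, "R3_elements")
  if (any(!is.na(mol$atoms$isotope))) v <- c(v, "R4_isotopes")
  if (rec$bond_count < 5L || rec$bond_count > 40L) v <- c(v, "R5_bond_count")
  if (any(mol$atoms$charge != 0L)) v <- c(v, "R6_charges")
  if (any(mol$atoms$element == "H")) v <- c(v, "R7_explicit_hydrogen")
  if (nchar(rec$canonical_smiles) >= 40L) v <- c(v, "R8_smiles_length")
  v
}

#' Curate a stream of structure strings
#'
#' Applies [check_rules()] to every input; molecules violating no rule are
#' accepted in input order. Parse failures never abort the stream: they are
#' counted separately in the report.
#'
#' @param records character vector of SMILES strings, or a data.frame with
#'   columns `id` and `smiles`
#' @return list with `accepted` (list of `ocsr_molrec`) and `report` (class
#'   `ocsr_curation_report`: `n_input`, `n_accepted`, `n_parse_failures`,
#'   `rejections` named integer vector rule -> count)
#' @export
curate_stream <- function(records) {
  if (is.data.frame(records)) {
    ids <- as.character(records$id)
    smis <- as.character(records$smiles)
  } else {
    smis <- as.character(records)
    ids <- rep(NA_character_, length(smis))
  }
  rejections <- stats::setNames(integer(length(.ocsr_rules)), .ocsr_rules)
  accepted <- list()
  n_parse_failures <- 0L
  n_rejected <- 0L
  for (i in seq_along(smis)) {
    rec <- tryCatch(
      molecule_record(smis[i], id = if (is.na(ids[i])) NULL else ids[i]),
      ocsr_error = function(e) NULL)
    if (is.null(rec)) { n_parse_failures <- n_parse_failures + 1L; next }
    viol <- check_rules(rec)
    if (length(viol) == 0L) {
      accepted[[length(accepted) + 1L]] <- rec
    } else {
      n_rejected <- n_rejected + 1L
      rejections[viol] <- rejections[viol] + 1L
    }
  }
  report <- structure(list(
    n_input = length(smis),
    n_accepted = length(accepted),
    n_parse_failures = n_parse_failures,
    rejections = rejections
  ), class = "ocsr_curation_report")
  list(accepted = accepted, report = report)
}

#' @export
print.ocsr_curation_report <- function(x, ...) {
  cat(sprintf("<curation report> %d in, %d accepted, %d parse failures\n",
              x$n_input, x$n_accepted, x$n_parse_failures))
  nz <- x$rejections[x$rejections > 0]
  if (length(nz)) for (r in names(nz)) cat(sprintf("  %s: %d\n", r, nz[[r]]))
  invisible(x)
}

#' Read a SMILES stream from a text file
#'
#' One SMILES per line; an optional leading tab-separated id column; lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path file path
#' @return data.frame with columns `id`, `smiles`
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  has_tab <- grepl("\t", lines, fixed = TRUE)
  ids <- character(length(lines)); smis <- character(length(lines))
  for (i in seq_along(lines)) {
    if (has_tab[i]) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      ids[i] <- parts[1]; smis[i] <- parts[2]
    } else {
      ids[i] <- sprintf("mol%05d", i); smis[i] <- lines[i]
    }
  }
  data.frame(id = ids, smiles = smis, stringsAsFactors = FALSE)
}

#' Write accepted molecules and a curation report
#'
#' @param curated result of [curate_stream()]
#' @param tsv_path output path for the accepted set (`id<TAB>smiles`)
#' @param report_path optional path for the JSON report
#' @return invisibly, the curated input
#' @export
write_curation <- function(curated, tsv_path, report_path = NULL) {
  rows <- vapply(curated$accepted,
                 function(r) paste(r$id, r$canonical_smiles, sep = "\t"), "")
  writeLines(rows, tsv_path)
  if (!is.null(report_path)) {
    rep <- curated$report
    jsonlite::write_json(list(
      n_input = rep$n_input, n_accepted = rep$n_accepted,
      n_parse_failures = rep$n_parse_failures,
      rejections = as.list(rep$rejections)
    ), report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(curated)
}
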