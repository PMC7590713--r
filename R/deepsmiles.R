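# DeepSMILES codec.
#
# DeepSMILES rewrites SMILES so a sequence generator never has to balance
# parentheses or pair ring-closure digits: open-parens are dropped (a
# k-atom branch is closed by k close-parens, each popping one atom from the
# derivation path) and a ring closure is written once, at the closing atom,
# as the ring SIZE (the number of atoms on the path from the closing atom up
# to and including its ring partner). "c1ccccc1" becomes "cccccc6",
# "CC(C)O" becomes "CCC)O".
#
# Encoding assumes ring closures bond to an ancestor on the derivation path,
# which holds for every string this package's canonical writer emits (ring
# bonds are DFS back edges).

.is_atom_token <- function(tok) {
  startsWith(tok, "[") | tok %in% c(.ocsr_organic, "b", "c", "n", "o", "p", "s")
}

.ring_size_token <- function(nsize) {
  if (nsize <= 9L) as.character(nsize) else sprintf("%%%02d", nsize)
}

#' Convert SMILES to DeepSMILES
#'
#' @param smiles a single-fragment SMILES string whose ring closures bond to
#'   derivation-path ancestors (canonical output of this package qualifies)
#' @return the DeepSMILES string
#' @examples
#' to_deepsmiles("c1ccccc1")  # "cccccc6"
#' to_deepsmiles("CC(C)O")    # "CCC)O"
#' @export
to_deepsmiles <- function(smiles) {
  toks <- .lex_smiles(smiles)
  out <- character(0)
  path <- integer(0)        # atom ids on the current derivation path
  branch_marks <- integer(0)
  n_atoms <- 0L
  ring_open <- list()       # digit -> list(atom, pos, bond)
  pending_bond <- ""
  atom_pos <- integer(0)    # atom id -> position on path when placed

  flush_bond <- function() {
    if (nzchar(pending_bond)) { out <<- c(out, pending_bond); pending_bond <<- "" }
  }
  for (tok in toks) {
    if (.is_atom_token(tok)) {
      flush_bond()
      out <- c(out, tok)
      n_atoms <- n_atoms + 1L
      path <- c(path, n_atoms)
    } else if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      if (nzchar(pending_bond)) stop(ocsr_condition("ocsr_invalid_structure",
        paste0("consecutive bond symbols in: ", smiles)))
      pending_bond <- tok
    } else if (tok == "(") {
      branch_marks <- c(branch_marks, length(path))
    } else if (tok == ")") {
      if (!length(branch_marks)) stop(ocsr_condition("ocsr_invalid_structure",
        paste0("unmatched ')' in: ", smiles)))
      mark <- branch_marks[length(branch_marks)]
      branch_marks <- branch_marks[-length(branch_marks)]
      out <- c(out, rep(")", length(path) - mark))
      path <- path[seq_len(mark)]
    } else if (grepl("^[0-9]$", tok) || startsWith(tok, "%")) {
      key <- sub("^%", "", tok)
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = path[length(path)],
                                 pos = length(path), bond = pending_bond)
        pending_bond <- ""
      } else {
        open <- ring_open[[key]]
        ring_open[[key]] <- NULL
        opos <- match(open$atom, path)
        if (is.na(opos)) stop(ocsr_condition("ocsr_invalid_structure",
          paste0("ring closure to non-ancestor atom in: ", smiles)))
        sym <- if (nzchar(pending_bond)) pending_bond else open$bond
        pending_bond <- ""
        out <- c(out, paste0(sym, .ring_size_token(length(path) - opos + 1L)))
      }
    } else if (tok == ".") {
      stop(ocsr_condition("ocsr_invalid_structure",
        "multi-fragment SMILES cannot be encoded as DeepSMILES"))
    } else {
      stop(ocsr_condition("ocsr_invalid_structure",
        paste0("unexpected token '", tok, "' in: ", smiles)))
    }
  }
  if (length(ring_open)) stop(ocsr_condition("ocsr_invalid_structure",
    paste0("unmatched ring closure in: ", smiles)))
  paste(out, collapse = "")
}

# Parse one atom token (as produced by the lexer) into atom properties.
.parse_atom_token <- function(tok) {
  if (startsWith(tok, "[")) {
    body <- substr(tok, 2L, nchar(tok) - 1L)
    m <- regexec(
      "^([0-9]+)?([A-Z][a-z]?|[a-z]{1,2}|\\*)(@{1,2})?(H([0-9]+)?)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
      body)
    parts <- regmatches(body, m)[[1]]
    if (length(parts) == 0L) stop(ocsr_condition("ocsr_invalid_structure",
      paste0("bad bracket atom ", tok)))
    sym <- parts[3]
    aromatic <- sym == tolower(sym) && sym != "*"
    element <- paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
    hcount <- 0L
    if (nzchar(parts[5])) hcount <- if (nzchar(parts[6])) as.integer(parts[6]) else 1L
    charge <- 0L
    cs <- parts[7]
    if (nzchar(cs)) {
      if (grepl("^[+-][0-9]+$", cs)) {
        charge <- as.integer(substr(cs, 2L, nchar(cs)))
        if (substr(cs, 1L, 1L) == "-") charge <- -charge
      } else charge <- nchar(cs) * (if (substr(cs, 1L, 1L) == "+") 1L else -1L)
    }
    list(element = element, aromatic = aromatic, charge = charge,
         isotope = if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_,
         hcount = hcount, bracket = TRUE)
  } else {
    aromatic <- tok %in% c("b", "c", "n", "o", "p", "s")
    element <- if (aromatic) toupper(tok) else tok  # Cl/Br stay two-letter
    list(element = element, aromatic = aromatic, charge = 0L,
         isotope = NA_integer_, hcount = NA_integer_, bracket = FALSE)
  }
}

# Assemble an ocsr_mol from parallel atom/bond accumulators.
.build_mol <- function(atoms, bonds, label) {
  atoms_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    isotope = vapply(atoms, `[[`, 0L, "isotope"),
    hcount = vapply(atoms, `[[`, 0L, "hcount"),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE)
  bonds_df <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, `[[`, 0L, "a1"),
    a2 = vapply(bonds, `[[`, 0L, "a2"),
    order = vapply(bonds, `[[`, 0L, "order"),
    aromatic = vapply(bonds, `[[`, FALSE, "aromatic"))
  else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                  aromatic = logical(0))
  mol <- structure(list(atoms = atoms_df, bonds = bonds_df, smiles = label),
                   class = "ocsr_mol")
  mol$atoms$hcount <- .implicit_hydrogens(mol)
  .perceive_aromaticity(mol)
}

#' Convert DeepSMILES back to SMILES
#'
#' Rebuilds the molecular graph from the DeepSMILES derivation (')' pops one
#' atom; a ring-size number bonds the current atom to the atom that many
#' positions up the derivation path) and emits this package's canonical
#' SMILES. Undecodable input (dangling ring size, ')' on an empty path, bad
#' atom token) signals `ocsr_invalid_structure`, which the evaluation module
#' counts as an invalid prediction.
#'
#' @param deepsmiles a DeepSMILES string
#' @return a canonical SMILES string
#' @export
from_deepsmiles <- function(deepsmiles) {
  toks <- tryCatch(.lex_smiles(deepsmiles), ocsr_error = function(e)
    stop(ocsr_condition("ocsr_invalid_structure", conditionMessage(e))))
  atoms <- list(); bonds <- list()
  path <- integer(0)
  pending_bond <- ""
  bond_order <- function(sym, a1, a2) {
    if (sym == "=") list(order = 2L, aromatic = FALSE)
    else if (sym == "#") list(order = 3L, aromatic = FALSE)
    else if (sym == ":") list(order = 1L, aromatic = TRUE)
    else list(order = 1L,
              aromatic = sym == "" && atoms[[a1]]$aromatic && atoms[[a2]]$aromatic)
  }
  for (tok in toks) {
    if (.is_atom_token(tok)) {
      atoms[[length(atoms) + 1L]] <- .parse_atom_token(tok)
      idx <- length(atoms)
      if (length(path)) {
        b <- bond_order(pending_bond, path[length(path)], idx)
        bonds[[length(bonds) + 1L]] <- list(a1 = path[length(path)], a2 = idx,
                                            order = b$order, aromatic = b$aromatic)
      }
      pending_bond <- ""
      path <- c(path, idx)
    } else if (tok %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- tok
    } else if (tok == ")") {
      if (length(path) <= 1L) stop(ocsr_condition("ocsr_invalid_structure",
        paste0("')' pops an empty derivation path in: ", deepsmiles)))
      path <- path[-length(path)]
    } else if (grepl("^[0-9]$", tok) || startsWith(tok, "%")) {
      nsize <- as.integer(sub("^%", "", tok))
      if (nsize < 3L || nsize > length(path)) {
        stop(ocsr_condition("ocsr_invalid_structure",
          sprintf("dangling ring size %d (path depth %d) in: %s",
                  nsize, length(path), deepsmiles)))
      }
      cur <- path[length(path)]
      partner <- path[length(path) - nsize + 1L]
      b <- bond_order(pending_bond, partner, cur)
      pending_bond <- ""
      bonds[[length(bonds) + 1L]] <- list(a1 = partner, a2 = cur,
                                          order = b$order, aromatic = b$aromatic)
    } else {
      stop(ocsr_condition("ocsr_invalid_structure",
        paste0("unexpected token '", tok, "' in DeepSMILES: ", deepsmiles)))
    }
  }
  if (!length(atoms)) stop(ocsr_condition("ocsr_invalid_structure",
    "empty DeepSMILES"))
  mol_to_smiles(.build_mol(atoms, bonds, deepsmiles))
}
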