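# SMILES parser producing an `ocsr_mol` molecular graph.
#
# Supported grammar: organic-subset atoms (B C N O P S F Cl Br I, aromatic
# b c n o p s), bracket atoms with isotope / chirality / H-count / charge /
# atom-map, bonds - = # : / \, branches, ring closures (digits and %nn) and
# dot-separated fragments. Chirality and directional bonds are parsed and
# carried but play no role downstream.

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string
#' @return an object of class `ocsr_mol`: a list with `atoms` (data.frame:
#'   element, aromatic, charge, isotope, hcount, explicit_h, bracket),
#'   `bonds` (data.frame: a1, a2, order, aromatic) and `smiles` (the input).
#'   Hydrogens written as bracket atoms remain graph nodes; all other
#'   hydrogens are implicit counts on their heavy atom.
#' @examples
#' m <- parse_smiles("c1ccccc1")
#' nrow(m$atoms)  # 6
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop(ocsr_condition("ocsr_parse_error", "empty or non-string SMILES input",
                        smiles = smiles))
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(element, aromatic, charge, isotope, hcount NA=implicit)
  bonds <- list()   # each: list(a1, a2, order, aromatic)
  stack <- integer(0)   # open branch attachment points
  prev <- 0L            # current attachment atom (0 = none, fragment start)
  pending_bond <- ""    # bond symbol awaiting next atom
  ring <- list()        # ring-closure digit -> list(atom, bond)

  fail <- function(msg, at = NA_integer_) {
    stop(ocsr_condition("ocsr_parse_error",
      sprintf("SMILES parse error at position %s: %s (input: %s)",
              ifelse(is.na(at), "?", at), msg, smiles),
      smiles = smiles))
  }

  add_atom <- function(element, aromatic, charge = 0L, isotope = NA_integer_,
                       hcount = NA_integer_, bracket = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = as.integer(charge),
      isotope = as.integer(isotope), hcount = as.integer(hcount),
      bracket = bracket)
    idx <- length(atoms)
    if (prev > 0L) {
      bond_sym <- pending_bond
      arom_bond <- FALSE
      order <- 1L
      if (bond_sym == "=") order <- 2L
      else if (bond_sym == "#") order <- 3L
      else if (bond_sym == ":") { order <- 1L; arom_bond <- TRUE }
      else if (bond_sym %in% c("", "/", "\\", "-")) {
        order <- 1L
        if (bond_sym == "" && aromatic && atoms[[prev]]$aromatic) arom_bond <- TRUE
      }
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx,
                                           order = order, aromatic = arom_bond)
    }
    pending_bond <<- ""
    prev <<- idx
    idx
  }

  close_ring <- function(digit, pos) {
    if (prev == 0L) fail("ring closure before any atom", pos)
    key <- as.character(digit)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- ""
    } else {
      open <- ring[[key]]
      ring[[key]] <<- NULL
      if (open$atom == prev) fail("ring closure bonds atom to itself", pos)
      sym <- if (nzchar(pending_bond)) pending_bond else open$bond
      pending_bond <<- ""
      order <- 1L; arom <- FALSE
      if (sym == "=") order <- 2L
      else if (sym == "#") order <- 3L
      else if (sym == ":") arom <- TRUE
      else if (sym == "") {
        if (atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic) arom <- TRUE
      }
      bonds[[length(bonds) + 1L]] <<- list(a1 = open$atom, a2 = prev,
                                           order = order, aromatic = arom)
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (nzchar(pending_bond)) fail("two consecutive bond symbols", i)
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) fail("branch opened before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched closing parenthesis", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      if (nzchar(pending_bond)) fail("bond symbol before dot", i)
      prev <- 0L
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch), i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        fail("%% ring closure needs two digits", i)
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unclosed bracket atom", i)
      body <- substr(smiles, i + 1L, j - 1L)
      m <- regexec(
        "^([0-9]+)?([A-Z][a-z]?|[a-z]{1,2}|\\*)(@{1,2})?(H([0-9]+)?)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
        body)
      parts <- regmatches(body, m)[[1]]
      if (length(parts) == 0L) fail(paste0("bad bracket atom [", body, "]"), i)
      isotope <- if (nzchar(parts[2])) as.integer(parts[2]) else NA_integer_
      sym <- parts[3]
      aromatic <- sym == tolower(sym) && sym != "*"
      element <- if (sym == "*") "*" else {
        e <- paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
        e
      }
      if (aromatic && !(element %in% .ocsr_aromatic_ok))
        fail(paste0("element cannot be aromatic: ", sym), i)
      hcount <- 0L
      if (nzchar(parts[5])) hcount <- if (nzchar(parts[6])) as.integer(parts[6]) else 1L
      charge <- 0L
      cs <- parts[7]
      if (nzchar(cs)) {
        if (grepl("^[+-][0-9]+$", cs)) {
          charge <- as.integer(substr(cs, 2L, nchar(cs)))
          if (substr(cs, 1L, 1L) == "-") charge <- -charge
        } else {
          charge <- nchar(cs) * (if (substr(cs, 1L, 1L) == "+") 1L else -1L)
        }
      }
      add_atom(element, aromatic, charge, isotope, hcount, bracket = TRUE)
      i <- j + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE)
        i <- i + 1L
      } else {
        fail(paste0("unknown atom symbol '", ch, "'"), i)
      }
    } else {
      fail(paste0("unexpected character '", ch, "'"), i)
    }
  }
  if (length(stack) > 0L) fail("unclosed branch parenthesis")
  if (length(ring) > 0L) fail("unmatched ring closure digit")
  if (length(atoms) == 0L) fail("no atoms")

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
    aromatic = vapply(bonds, `[[`, FALSE, "aromatic"),
    stringsAsFactors = FALSE)
  else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                  aromatic = logical(0))

  mol <- structure(list(atoms = atoms_df, bonds = bonds_df, smiles = smiles),
                   class = "ocsr_mol")
  # hydrogen counts are fixed by the bond orders as written (Kekule or
  # aromatic); perception afterwards must not change them
  mol$atoms$hcount <- .implicit_hydrogens(mol)
  .perceive_aromaticity(mol)
}

# Implicit-H assignment. Bracket atoms keep their written count; organic
# subset atoms get the lowest standard valence covering their bond-order sum
# (aromatic bonds count 1.5, floor of the sum, matching common practice).
.implicit_hydrogens <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  nh <- atoms$hcount
  bsum <- numeric(nrow(atoms))
  if (nrow(bonds)) {
    ord <- ifelse(bonds$aromatic, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + ord[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + ord[k]
    }
  }
  for (i in seq_len(nrow(atoms))) {
    if (atoms$bracket[i]) next  # explicit count from the brackets
    vlist <- .ocsr_valences[[atoms$element[i]]]
    if (is.null(vlist)) { nh[i] <- 0L; next }
    b <- as.integer(floor(bsum[i]))
    if (atoms$aromatic[i]) {
      # aromatic atoms never promote to a higher valence (an n with three
      # connections has no H, it is not pentavalent)
      nh[i] <- max(0L, vlist[1] - b)
    } else {
      v <- vlist[vlist >= b]
      nh[i] <- if (length(v)) as.integer(v[1] - b) else 0L
    }
  }
  nh
}

#' Number of connected components (fragments) of a molecule
#' @param mol an `ocsr_mol`
#' @return integer fragment count, >= 1
#' @export
fragment_count <- function(mol) {
  n <- nrow(mol$atoms)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    r1 <- find(mol$bonds$a1[k]); r2 <- find(mol$bonds$a2[k])
    if (r1 != r2) parent[r1] <- r2
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

#' Molecular weight in Daltons (average atomic masses, implicit H included)
#' @param mol an `ocsr_mol`
#' @return numeric molecular weight
#' @export
mol_weight <- function(mol) {
  heavy <- sum(.ocsr_element_mass(mol$atoms$element[mol$atoms$element != "*"]))
  # isotope-labelled atoms still use average mass: the label is a curation
  # rejection criterion, not a mass correction, at this pipeline's scale
  heavy + sum(mol$atoms$hcount) * .ocsr_masses[["H"]]
}

#' Number of bonds (graph edges; a double bond counts once)
#' @param mol an `ocsr_mol`
#' @return integer bond count
#' @export
bond_count <- function(mol) nrow(mol$bonds)

#' Smallest-set-of-smallest-rings ring count (cyclomatic number)
#' @param mol an `ocsr_mol`
#' @return integer ring count
#' @export
ring_count <- function(mol) {
  nrow(mol$bonds) - nrow(mol$atoms) + fragment_count(mol)
}

#' @export
print.ocsr_mol <- function(x, ...) {
  cat(sprintf("<ocsr_mol> %d atoms, %d bonds: %s\n",
              nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}

# Adjacency list: for each atom, data.frame(nbr, bond_index)
.adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(0), bond = integer(0))
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]]$nbr <- c(adj[[a]]$nbr, b); adj[[a]]$bond <- c(adj[[a]]$bond, k)
    adj[[b]]$nbr <- c(adj[[b]]$nbr, a); adj[[b]]$bond <- c(adj[[b]]$bond, k)
  }
  adj
}
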