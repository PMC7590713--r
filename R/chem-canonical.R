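# Canonical SMILES generation: iterative (Morgan-style) invariant refinement
# to rank atoms, then a rank-guided DFS emitter. Two SMILES spellings of the
# same molecule (after aromaticity perception) map to the same output string.

.canonical_ranks <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .adjacency(mol)
  iso <- ifelse(is.na(mol$atoms$isotope), 0L, mol$atoms$isotope)
  base <- paste(
    match(mol$atoms$element, c(names(.ocsr_masses), "*")),
    as.integer(mol$atoms$aromatic),
    mol$atoms$charge,
    mol$atoms$hcount,
    vapply(seq_len(n), function(i) length(adj[[i]]$nbr), 0L),
    iso, sep = "|")
  rank <- match(base, sort(unique(base))) - 1L

  bondcode <- ifelse(mol$bonds$aromatic, 5L, mol$bonds$order)
  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        nb <- adj[[i]]$nbr
        bc <- bondcode[adj[[i]]$bond]
        ord <- order(bc, rank[nb])
        paste(formatC(rank[i], width = 6, flag = "0"),
              paste(bc[ord], formatC(rank[nb][ord], width = 6, flag = "0"),
                    sep = ":", collapse = ","), sep = ";")
      }, "")
      new_rank <- match(key, sort(unique(key))) - 1L
      if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  # tie-break: promote one atom of the first tied class, re-refine
  while (length(unique(rank)) < n) {
    tied_vals <- sort(unique(rank[duplicated(rank)]))
    cls <- which(rank == tied_vals[1])
    rank <- rank * 2L
    rank[cls[1]] <- rank[cls[1]] - 1L
    rank <- refine(match(rank, sort(unique(rank))) - 1L)
  }
  rank
}

.atom_default_h <- function(element, bondsum, aromatic = FALSE) {
  vlist <- .ocsr_valences[[element]]
  if (is.null(vlist)) return(NA_integer_)
  b <- as.integer(floor(bondsum))
  if (aromatic) return(max(0L, vlist[1] - b))
  v <- vlist[vlist >= b]
  if (length(v)) as.integer(v[1] - b) else 0L
}

.atom_token <- function(mol, adj, i) {
  a <- mol$atoms[i, ]
  sym <- if (a$aromatic) tolower(a$element) else a$element
  bsum <- {
    bidx <- adj[[i]]$bond
    sum(ifelse(mol$bonds$aromatic[bidx], 1.5, mol$bonds$order[bidx]))
  }
  plain_ok <- a$element %in% .ocsr_organic && a$charge == 0L &&
    is.na(a$isotope) &&
    (!a$aromatic || tolower(a$element) %in% c("b", "c", "n", "o", "p", "s")) &&
    identical(a$hcount, .atom_default_h(a$element, bsum, a$aromatic))
  if (plain_ok) return(sym)
  h <- if (a$hcount == 0L) "" else if (a$hcount == 1L) "H" else paste0("H", a$hcount)
  chg <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else if (a$charge == -1L) "-"
         else if (a$charge > 0L) paste0("+", a$charge) else paste0("-", abs(a$charge))
  isot <- if (is.na(a$isotope)) "" else as.character(a$isotope)
  paste0("[", isot, sym, h, chg, "]")
}

.bond_token <- function(mol, k, from, to) {
  b <- mol$bonds[k, ]
  if (b$aromatic) return("")
  if (b$order == 2L) return("=")
  if (b$order == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl)
  if (mol$atoms$aromatic[from] && mol$atoms$aromatic[to]) return("-")
  ""
}

#' Write a molecule as a canonical SMILES string
#'
#' @param mol an `ocsr_mol`
#' @return a SMILES string; deterministic for a given molecular graph,
#'   independent of the atom order of the input
#' @export
mol_to_smiles <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .adjacency(mol)
  rank <- .canonical_ranks(mol)

  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]$nbr) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }

  emit_component <- function(members) {
    start <- members[order(rank[members])][1]
    visited <- rep(FALSE, n)
    bond_used <- rep(FALSE, nrow(mol$bonds))
    ring_digit <- list()   # per atom: character vector of digit tokens (with bond syms)
    for (i in seq_len(n)) ring_digit[[i]] <- character(0)
    next_digit <- 0L
    digit_token <- function() {
      next_digit <<- next_digit + 1L
      if (next_digit <= 9L) as.character(next_digit) else sprintf("%%%02d", next_digit)
    }

    # first pass: DFS records the spanning tree (children in rank order) and
    # assigns ring-closure digits to back edges
    children_of <- vector("list", n)
    discover <- function(v) {
      visited[v] <<- TRUE
      nb <- adj[[v]]$nbr; bd <- adj[[v]]$bond
      ord <- order(rank[nb])
      for (j in ord) {
        w <- nb[j]; k <- bd[j]
        if (bond_used[k]) next
        bond_used[k] <<- TRUE
        if (visited[w]) {
          d <- digit_token()
          sym <- .bond_token(mol, k, v, w)
          ring_digit[[w]] <<- c(ring_digit[[w]], d)          # opening: bare digit
          ring_digit[[v]] <<- c(ring_digit[[v]], paste0(sym, d))  # closing carries bond
        } else {
          children_of[[v]] <<- c(children_of[[v]], list(list(w = w, k = k)))
          discover(w)
        }
      }
    }
    discover(start)

    emit <- function(v) {
      out <- paste0(.atom_token(mol, adj, v), paste(ring_digit[[v]], collapse = ""))
      children <- children_of[[v]]
      for (ci in seq_along(children)) {
        ch <- children[[ci]]
        sub <- paste0(.bond_token(mol, ch$k, v, ch$w), emit(ch$w))
        out <- if (ci < length(children)) paste0(out, "(", sub, ")")
               else paste0(out, sub)
      }
      out
    }
    emit(start)
  }

  parts <- vapply(sort(unique(comp)), function(ci) emit_component(which(comp == ci)), "")
  paste(sort(parts), collapse = ".")
}

#' Canonicalize a SMILES string
#'
#' Parses the input (with aromaticity perception) and re-emits it as this
#' package's canonical SMILES. Idempotent; two spellings of the same molecule
#' give the same output.
#'
#' @param smiles a single SMILES string
#' @return the canonical SMILES string
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' @export
canonicalize <- function(smiles) {
  mol_to_smiles(parse_smiles(smiles))
}

#' Test whether two SMILES denote the same molecule
#' @param a,b SMILES strings
#' @return TRUE when the canonical forms are equal
#' @export
same_molecule <- function(a, b) {
  identical(canonicalize(a), canonicalize(b))
}
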