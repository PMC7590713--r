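# SELFIES codec.
#
# SELFIES strings are sequences of bracketed symbols with a derivation
# grammar that makes (essentially) every symbol sequence decode to a valid
# molecule: bond orders are capped by the valence of both partners, branch
# lengths and ring distances are read from index symbols, and symbols that
# cannot be realized are skipped. The codec follows the v2 conventions:
# 16-symbol index alphabet, [BranchN]/[RingN] with N index symbols,
# Q = q1*16 + q2 ... , branch length Q+1 symbols, ring partner Q+1 atoms
# back in derivation order. Aromatic systems are kekulized before encoding
# (SELFIES has no aromatic symbols).

.selfies_index_alphabet <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[=Branch1]", "[#Branch1]",
  "[Branch2]", "[=Branch2]", "[#Branch2]", "[O]", "[N]", "[=N]", "[=C]",
  "[#C]", "[S]", "[P]")

# valence caps for decoding: lowest standard valence is the default H fill,
# the max listed valence is the bonding capacity
.selfies_cap <- function(element) {
  vlist <- .ocsr_valences[[element]]
  if (is.null(vlist)) 8L else as.integer(max(vlist))
}

.selfies_index_value <- function(sym) {
  i <- match(sym, .selfies_index_alphabet)
  if (is.na(i)) 0L else i - 1L  # unknown index symbols read as 0 (total decode)
}

.selfies_index_symbols <- function(q, n) {
  out <- character(n)
  for (i in n:1) { out[i] <- .selfies_index_alphabet[q %% 16L + 1L]; q <- q %/% 16L }
  out
}

.selfies_bond_prefix <- function(order) c("", "=", "#")[order]

# atom symbol for the encoder; H spec only when the count differs from the
# default valence fill of the kekulized graph
.selfies_atom_symbol <- function(mol, adj, i, bond_to_parent) {
  a <- mol$atoms[i, ]
  bsum <- sum(mol$bonds$order[adj[[i]]$bond])
  default_h <- .atom_default_h(a$element, bsum)
  hspec <- if (!identical(a$hcount, default_h)) paste0("H", a$hcount) else ""
  chg <- if (a$charge == 0L) "" else if (a$charge > 0L) paste0("+", a$charge)
         else paste0("-", abs(a$charge))
  paste0("[", .selfies_bond_prefix(bond_to_parent), a$element, hspec, chg, "]")
}

#' Convert SMILES to SELFIES
#'
#' The molecule is kekulized, then linearized by a DFS whose branches become
#' `[BranchN]` constructs and whose ring back-edges become `[RingN]`
#' constructs with derivation-order distances.
#'
#' @param smiles a single-fragment SMILES string
#' @return the SELFIES string
#' @examples
#' to_selfies("CCO")  # "[C][C][O]"
#' @export
to_selfies <- function(smiles) {
  mol <- .kekulize(parse_smiles(smiles))
  if (fragment_count(mol) != 1L) stop(ocsr_condition("ocsr_invalid_structure",
    "multi-fragment SMILES cannot be encoded as SELFIES"))
  n <- nrow(mol$atoms)
  adj <- .adjacency(mol)

  # DFS pre-order; back edges recorded at the deeper atom
  preorder <- integer(0)
  pos <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  bond_used <- rep(FALSE, nrow(mol$bonds))
  rings_at <- vector("list", n)   # atom -> list(partner, order)
  children_of <- vector("list", n)
  discover <- function(v) {
    visited[v] <<- TRUE
    preorder <<- c(preorder, v)
    pos[v] <<- length(preorder)
    for (j in seq_along(adj[[v]]$nbr)) {
      w <- adj[[v]]$nbr[j]; k <- adj[[v]]$bond[j]
      if (bond_used[k]) next
      bond_used[k] <<- TRUE
      if (visited[w]) {
        rings_at[[v]] <<- c(rings_at[[v]],
                            list(list(partner = w, order = mol$bonds$order[k])))
      } else {
        children_of[[v]] <<- c(children_of[[v]],
                               list(list(w = w, order = mol$bonds$order[k])))
        discover(w)
      }
    }
  }
  discover(1L)

  emit <- function(v, bond_to_parent) {
    out <- .selfies_atom_symbol(mol, adj, v, bond_to_parent)
    for (rg in rings_at[[v]]) {
      q <- pos[v] - pos[rg$partner] - 1L
      pre <- .selfies_bond_prefix(rg$order)
      if (q < 16L) out <- c(out, paste0("[", pre, "Ring1]"), .selfies_index_symbols(q, 1L))
      else if (q < 256L) out <- c(out, paste0("[", pre, "Ring2]"), .selfies_index_symbols(q, 2L))
      else out <- c(out, paste0("[", pre, "Ring3]"), .selfies_index_symbols(q, 3L))
    }
    children <- children_of[[v]]
    for (ci in seq_along(children)) {
      ch <- children[[ci]]
      sub <- emit(ch$w, ch$order)
      if (ci < length(children)) {
        q <- length(sub) - 1L
        pre <- .selfies_bond_prefix(ch$order)
        if (q < 16L) out <- c(out, paste0("[", pre, "Branch1]"), .selfies_index_symbols(q, 1L), sub)
        else if (q < 256L) out <- c(out, paste0("[", pre, "Branch2]"), .selfies_index_symbols(q, 2L), sub)
        else out <- c(out, paste0("[", pre, "Branch3]"), .selfies_index_symbols(q, 3L), sub)
      } else {
        out <- c(out, sub)
      }
    }
    out
  }
  paste(emit(1L, 1L), collapse = "")
}

#' Convert SELFIES back to SMILES
#'
#' Total on sequences of well-formed symbols: bond orders are capped by the
#' remaining valence of both partners, atoms that cannot bond are dropped,
#' out-of-range ring distances are clamped, duplicate ring bonds skipped.
#' Only an empty derivation (no atom realized) signals
#' `ocsr_invalid_structure`.
#'
#' @param selfies a SELFIES string
#' @return a canonical SMILES string
#' @export
from_selfies <- function(selfies) {
  syms <- tryCatch(.lex_selfies(selfies), ocsr_error = function(e)
    stop(ocsr_condition("ocsr_invalid_structure", conditionMessage(e))))
  st <- new.env(parent = emptyenv())
  st$atoms <- list(); st$bonds <- list(); st$capacity <- integer(0)

  parse_sym <- function(sym) {
    body <- substr(sym, 2L, nchar(sym) - 1L)
    m <- regexec("^([=#]?)(Branch|Ring)([123])$", body)
    p <- regmatches(body, m)[[1]]
    if (length(p)) {
      return(list(kind = tolower(p[3]), order = match(p[2], c("", "=", "#")),
                  nidx = as.integer(p[4])))
    }
    m <- regexec("^([=#]?)([A-Z][a-z]?)(H([0-9]))?([+-][0-9]?)?$", body)
    p <- regmatches(body, m)[[1]]
    if (length(p) && !is.null(.ocsr_valences[[p[3]]])) {
      hc <- if (nzchar(p[4])) as.integer(p[5]) else NA_integer_
      chg <- 0L
      if (nzchar(p[6])) {
        d <- substr(p[6], 2L, 2L)
        chg <- (if (nzchar(d)) as.integer(d) else 1L) *
               (if (startsWith(p[6], "-")) -1L else 1L)
      }
      return(list(kind = "atom", order = match(p[2], c("", "=", "#")),
                  element = p[3], hcount = hc, charge = chg))
    }
    list(kind = "skip")
  }

  add_atom <- function(s, attach) {
    cap <- .selfies_cap(s$element)
    if (!is.na(s$hcount)) cap <- max(0L, cap - s$hcount)
    if (attach > 0L) {
      ord <- min(s$order, st$capacity[attach], cap)
      if (ord <= 0L) return(0L)  # cannot bond: drop the atom
      st$atoms[[length(st$atoms) + 1L]] <- list(
        element = s$element, aromatic = FALSE, charge = s$charge,
        isotope = NA_integer_, hcount = s$hcount, bracket = !is.na(s$hcount))
      idx <- length(st$atoms)
      st$bonds[[length(st$bonds) + 1L]] <- list(a1 = attach, a2 = idx,
                                                order = ord, aromatic = FALSE)
      st$capacity[attach] <- st$capacity[attach] - ord
      st$capacity[idx] <- cap - ord
      idx
    } else {
      st$atoms[[length(st$atoms) + 1L]] <- list(
        element = s$element, aromatic = FALSE, charge = s$charge,
        isotope = NA_integer_, hcount = s$hcount, bracket = !is.na(s$hcount))
      st$capacity[length(st$atoms)] <- cap
      length(st$atoms)
    }
  }

  read_q <- function(syms, i, nidx) {
    q <- 0L
    for (j in seq_len(nidx)) {
      q <- q * 16L
      if (i + j <= length(syms)) q <- q + .selfies_index_value(syms[i + j])
    }
    q
  }

  # derive syms[from..to] with `attach` as the current head atom
  derive <- function(syms, from, to, attach) {
    i <- from
    head <- attach
    while (i <= to) {
      s <- parse_sym(syms[i])
      if (s$kind == "atom") {
        idx <- add_atom(s, head)
        if (idx > 0L) head <- idx
        i <- i + 1L
      } else if (s$kind == "branch") {
        q <- read_q(syms, i, s$nidx)
        len <- q + 1L
        bstart <- i + s$nidx + 1L
        bend <- min(to, bstart + len - 1L)
        if (head > 0L) {
          if (bstart <= to) derive(syms, bstart, bend, head)
          i <- bstart + len
        } else {
          i <- bstart  # no head atom: drop the branch symbol, keep the content
        }
      } else if (s$kind == "ring") {
        q <- read_q(syms, i, s$nidx)
        if (head > 0L) {
          back <- q + 1L
          partner <- max(1L, head - back)
          dup <- any(vapply(st$bonds, function(b)
            (b$a1 == partner & b$a2 == head) | (b$a1 == head & b$a2 == partner),
            FALSE))
          if (partner != head && !dup) {
            ord <- min(s$order, st$capacity[partner], st$capacity[head])
            if (ord > 0L) {
              st$bonds[[length(st$bonds) + 1L]] <- list(
                a1 = partner, a2 = head, order = ord, aromatic = FALSE)
              st$capacity[partner] <- st$capacity[partner] - ord
              st$capacity[head] <- st$capacity[head] - ord
            }
          }
        }
        i <- i + s$nidx + 1L
      } else {
        i <- i + 1L  # unrecognized symbol: skip (total decoding)
      }
    }
  }
  derive(syms, 1L, length(syms), 0L)

  if (!length(st$atoms)) stop(ocsr_condition("ocsr_invalid_structure",
    "SELFIES derivation produced no atoms"))
  mol_to_smiles(.build_mol(st$atoms, st$bonds, selfies))
}
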