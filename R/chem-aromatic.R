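# Aromaticity perception and kekulization.
#
# Perception uses a pragmatic Hueckel model on the smallest ring through each
# bond (sizes 5-7): an atom contributes 1 pi electron if it carries a double
# bond into the ring system, 2 if it is a heteroatom donating a lone pair,
# and a ring is aromatic when all members are eligible and the electron count
# is 4n+2. Rings written in lowercase (aromatic input) are trusted as given.
# This covers the chemistry the pipeline generates and the common literature
# motifs (benzene, pyridine, pyrrole, furan, thiophene, naphthalene); it is
# not a full electron-delocalization model.

# Smallest ring through each bond, as integer atom vectors; unique, size <= max_size.
.find_rings <- function(mol, max_size = 7L) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  adj <- .adjacency(mol)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    # BFS from a to b avoiding bond k
    n <- nrow(mol$atoms)
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[a] <- 0L
    queue <- a
    while (length(queue) && is.na(dist[b])) {
      v <- queue[1]; queue <- queue[-1]
      if (dist[v] >= max_size - 1L) next
      nbrs <- adj[[v]]$nbr[adj[[v]]$bond != k]
      for (w in nbrs) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[b])) next
    path <- b
    while (path[1] != a) path <- c(prev[path[1]], path)
    if (length(path) < 3L || length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- path
    }
  }
  rings
}

.ring_atom_set <- function(mol) {
  unique(unlist(.find_rings(mol, max_size = 12L)))
}

.perceive_aromaticity <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(mol)
  rings <- .find_rings(mol, max_size = 7L)
  if (!length(rings)) return(mol)
  adj <- .adjacency(mol)
  in_any_ring <- rep(FALSE, nrow(mol$atoms))
  for (r in rings) in_any_ring[r] <- TRUE

  # evaluate every ring against the original (frozen) bond orders, then mark:
  # fused systems must not see a half-converted neighbour ring
  mol0 <- mol
  to_mark <- list()
  for (r in rings) {
    atoms_in <- mol0$atoms[r, , drop = FALSE]
    if (all(atoms_in$aromatic)) {
      mark <- TRUE  # written aromatic: trust the input
    } else if (any(atoms_in$aromatic)) {
      next  # mixed rings are not re-perceived
    } else {
      if (length(r) < 5L) next
      pi <- 0L
      ok <- TRUE
      for (i in r) {
        bidx <- adj[[i]]$bond
        orders <- mol0$bonds$order[bidx]
        if (any(orders == 3L)) { ok <- FALSE; break }
        if (length(bidx) > 3L) { ok <- FALSE; break }
        dbl <- bidx[orders == 2L & !mol0$bonds$aromatic[bidx]]
        if (length(dbl) >= 1L) {
          partners <- ifelse(mol0$bonds$a1[dbl] == i, mol0$bonds$a2[dbl], mol0$bonds$a1[dbl])
          if (any(partners %in% r)) pi <- pi + 1L
          else if (any(in_any_ring[partners])) pi <- pi + 1L
          else if (mol0$atoms$element[i] == "C") { pi <- pi + 0L }  # exocyclic C=O etc.
          else { ok <- FALSE; break }
        } else {
          el <- mol0$atoms$element[i]
          if (el %in% c("N", "P", "O", "S", "Se") && mol0$atoms$charge[i] == 0L) {
            pi <- pi + 2L
          } else { ok <- FALSE; break }
        }
      }
      mark <- ok && (pi %% 4L == 2L)
    }
    if (mark) to_mark[[length(to_mark) + 1L]] <- r
  }
  for (r in to_mark) {
    mol$atoms$aromatic[r] <- TRUE
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$a1[k] %in% r && mol$bonds$a2[k] %in% r) {
        # only perimeter bonds of this ring
        pos1 <- match(mol$bonds$a1[k], r); pos2 <- match(mol$bonds$a2[k], r)
        d <- abs(pos1 - pos2)
        if (d == 1L || d == length(r) - 1L) {
          mol$bonds$aromatic[k] <- TRUE
          mol$bonds$order[k] <- 1L
        }
      }
    }
  }
  mol
}

# Replace aromatic bonds by an alternating single/double assignment.
# Keeps hydrogen counts (already fixed at parse time). Fails with an
# ocsr_kekulize_error when no perfect matching over the pi-requiring atoms
# exists.
.kekulize <- function(mol) {
  ar_bonds <- which(mol$bonds$aromatic)
  if (!length(ar_bonds)) return(mol)
  adj <- .adjacency(mol)
  n <- nrow(mol$atoms)
  deg <- vapply(seq_len(n), function(i) length(adj[[i]]$nbr), 0L)

  needs <- rep(FALSE, n)
  for (i in which(mol$atoms$aromatic)) {
    el <- mol$atoms$element[i]
    has_exo_double <- any(mol$bonds$order[adj[[i]]$bond] == 2L &
                          !mol$bonds$aromatic[adj[[i]]$bond])
    needs[i] <- if (el == "C") !has_exo_double
    else if (el %in% c("N", "P")) (mol$atoms$hcount[i] == 0L && deg[i] == 2L &&
                                   !has_exo_double)
    else FALSE
  }

  # backtracking perfect matching on `needs` atoms over aromatic bonds
  match_of <- rep(NA_integer_, n)
  ar_nbrs <- lapply(seq_len(n), function(i) {
    sel <- adj[[i]]$bond %in% ar_bonds
    adj[[i]]$nbr[sel]
  })
  todo <- which(needs)
  solve <- function(pos) {
    while (pos <= length(todo) && !is.na(match_of[todo[pos]])) pos <- pos + 1L
    if (pos > length(todo)) return(TRUE)
    i <- todo[pos]
    for (j in ar_nbrs[[i]]) {
      if (needs[j] && is.na(match_of[j])) {
        match_of[i] <<- j; match_of[j] <<- i
        if (solve(pos + 1L)) return(TRUE)
        match_of[i] <<- NA_integer_; match_of[j] <<- NA_integer_
      }
    }
    FALSE
  }
  if (!solve(1L)) {
    stop(ocsr_condition("ocsr_kekulize_error",
      paste0("cannot kekulize aromatic system: ", mol$smiles)))
  }
  for (k in ar_bonds) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    mol$bonds$order[k] <- if (!is.na(match_of[a]) && match_of[a] == b) 2L else 1L
    mol$bonds$aromatic[k] <- FALSE
  }
  mol$atoms$aromatic <- FALSE
  mol
}
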