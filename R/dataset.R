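# Dataset assembly: synthetic fixture molecules, packaging of
# (image, token-index) pairs into train/test splits, and batch streaming.
#
# The fixture generator stands in for a large public structure corpus: it
# assembles molecules by seeded random chain growth (optional branch,
# optional ring, occasional C=C double bond) over a small atom pool, then
# filters through the curation rules, so every emitted molecule is
# rule-compliant by construction and the package has zero data
# dependencies.

#' Fixture generator configuration
#'
#' @param n_molecules number of molecules to emit
#' @param seed integer seed; the generator is a deterministic function of it
#' @param ring_probability probability a molecule gets one ring (default 0.3)
#' @param branch_probability probability of one side branch (default 0.4)
#' @param double_bond_probability per-eligible-bond probability of a C=C
#'   (default 0.15)
#' @param atom_pool elements sampled for the backbone (subset of the curation
#'   whitelist; default weighted toward carbon)
#' @return object of class `ocsr_fixture_config`
#' @export
fixture_config <- function(n_molecules, seed = 1L, ring_probability = 0.3,
                           branch_probability = 0.4,
                           double_bond_probability = 0.15,
                           atom_pool = c("C", "C", "C", "C", "C", "N", "O", "O", "S")) {
  stopifnot(n_molecules >= 1L, all(atom_pool %in% .ocsr_allowed_elements))
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 ring_probability = ring_probability,
                 branch_probability = branch_probability,
                 double_bond_probability = double_bond_probability,
                 atom_pool = atom_pool),
            class = "ocsr_fixture_config")
}

# assemble one random molecule graph; may violate curation (caller filters)
.grow_molecule <- function(cfg) {
  m <- sample(6:16, 1L)
  # heteroatoms are separated by at least one carbon, as in typical organic
  # scaffolds (no peroxide/hydrazine runs)
  elements <- character(m)
  elements[1] <- "C"
  for (i in 2:m) {
    elements[i] <- if (elements[i - 1L] != "C") "C"
                   else sample(cfg$atom_pool, 1L)
  }
  elements[m] <- "C"
  atoms <- lapply(elements, function(e) list(
    element = e, aromatic = FALSE, charge = 0L, isotope = NA_integer_,
    hcount = NA_integer_, bracket = FALSE))
  bonds <- lapply(seq_len(m - 1L), function(i) list(
    a1 = i, a2 = i + 1L, order = 1L, aromatic = FALSE))
  nbonds <- function(i) sum(vapply(bonds, function(b) b$a1 == i || b$a2 == i, FALSE))
  in_double <- rep(FALSE, m + 8L)
  # occasional C=C on interior chain bonds
  for (k in seq_len(m - 1L)) {
    b <- bonds[[k]]
    if (elements[b$a1] == "C" && elements[b$a2] == "C" &&
        !in_double[b$a1] && !in_double[b$a2] &&
        stats::runif(1) < cfg$double_bond_probability) {
      bonds[[k]]$order <- 2L
      in_double[c(b$a1, b$a2)] <- TRUE
    }
  }
  # one optional ring: single bond between two interior carbons
  if (stats::runif(1) < cfg$ring_probability && m >= 7L) {
    size <- sample(5:6, 1L)
    i <- sample(seq_len(m - size + 1L), 1L)
    j <- i + size - 1L
    if (elements[i] == "C" && elements[j] == "C" &&
        !in_double[i] && !in_double[j]) {
      bonds[[length(bonds) + 1L]] <- list(a1 = i, a2 = j, order = 1L,
                                          aromatic = FALSE)
    }
  }
  # one optional short branch off an interior carbon
  if (stats::runif(1) < cfg$branch_probability) {
    host <- sample(2:(m - 1L), 1L)
    if (elements[host] == "C" && nbonds(host) <= 2L && !in_double[host]) {
      blen <- sample(1:2, 1L)
      pool <- c(cfg$atom_pool, "F", "Cl")
      for (bi in seq_len(blen)) {
        el <- if (bi == blen) sample(pool, 1L) else "C"
        atoms[[length(atoms) + 1L]] <- list(
          element = el, aromatic = FALSE, charge = 0L, isotope = NA_integer_,
          hcount = NA_integer_, bracket = FALSE)
        newi <- length(atoms)
        bonds[[length(bonds) + 1L]] <- list(
          a1 = if (bi == 1L) host else newi - 1L, a2 = newi,
          order = 1L, aromatic = FALSE)
        if (el %in% c("F", "Cl", "O", "S") && bi < blen) break
      }
    }
  }
  .build_mol(atoms, bonds, "<fixture>")
}

#' Generate curated synthetic fixture molecules
#'
#' Deterministic given `cfg$seed`; all outputs are distinct canonical SMILES
#' and pass [check_rules()] with zero violations.
#'
#' @param cfg a [fixture_config()] (or an integer, shorthand for
#'   `fixture_config(cfg)`)
#' @return list of `ocsr_molrec` with ids `fixNNNNN`
#' @export
generate_fixtures <- function(cfg) {
  if (is.numeric(cfg)) cfg <- fixture_config(cfg)
  stopifnot(inherits(cfg, "ocsr_fixture_config"))
  .with_seed(cfg$seed, {
    out <- list()
    seen <- character(0)
    budget <- 60L * cfg$n_molecules
    attempts <- 0L
    while (length(out) < cfg$n_molecules) {
      attempts <- attempts + 1L
      if (attempts > budget) stop(ocsr_condition("ocsr_generation_exhausted",
        sprintf("could not assemble %d curated molecules in %d attempts",
                cfg$n_molecules, budget)))
      mol <- tryCatch(.grow_molecule(cfg), ocsr_error = function(e) NULL)
      if (is.null(mol)) next
      rec <- tryCatch(molecule_record(mol_to_smiles(mol)),
                      ocsr_error = function(e) NULL)
      if (is.null(rec) || length(check_rules(rec)) > 0L) next
      if (rec$canonical_smiles %in% seen) next
      seen <- c(seen, rec$canonical_smiles)
      rec$id <- sprintf("fix%05d", length(out) + 1L)
      out[[length(out) + 1L]] <- rec
    }
    out
  })
}

# representation text of a curated record
.repr_text <- function(rec, representation) {
  switch(representation,
    smiles = rec$canonical_smiles,
    deepsmiles = to_deepsmiles(rec$canonical_smiles),
    selfies = to_selfies(rec$canonical_smiles))
}

#' Package molecules into a train/test dataset
#'
#' Renders every molecule (one seeded rotation each), featurizes the
#' bitmaps, tokenizes the chosen representation, builds the vocabulary on
#' the TRAIN split only, and assigns the split by a seeded shuffle. All
#' seeds are persisted in the returned manifest.
#'
#' @param mols list of `ocsr_molrec` (curated)
#' @param representation "smiles", "deepsmiles" or "selfies"
#' @param out_dir output directory (images, features, labels, vocabulary,
#'   manifest)
#' @param base_seed drives rotations and the split shuffle
#' @param test_fraction held-out fraction (default 0.1)
#' @param backbone featurizer backbone (default [default_backbone()])
#' @param canvas_px canvas size (default 299)
#' @return object of class `ocsr_dataset`: records (each with molecule_id,
#'   image_path, feature_path, features, target, text), split, vocab,
#'   pad_length, representation, base_seed
#' @export
package_dataset <- function(mols, representation = c("smiles", "deepsmiles", "selfies"),
                            out_dir, base_seed = 1L, test_fraction = 0.1,
                            backbone = default_backbone(), canvas_px = 299L) {
  representation <- match.arg(representation)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  feat_dir <- file.path(out_dir, "features")
  dir.create(feat_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- render_dataset(mols, img_dir, base_seed, canvas_px)
  ok_ids <- manifest$molecule_id
  mols <- mols[vapply(mols, function(r) r$id %in% ok_ids, FALSE)]
  n <- length(mols)
  stopifnot(n >= 2L)

  texts <- vapply(mols, .repr_text, "", representation)
  token_seqs <- lapply(texts, tokenize, representation = representation)

  n_test <- max(1L, round(n * test_fraction))
  ord <- .with_seed(base_seed, sample.int(n))
  test_idx <- sort(ord[seq_len(n_test)])
  is_test <- seq_len(n) %in% test_idx

  vocab <- build_vocabulary(token_seqs[!is_test])
  pad_length <- max(vocab$max_length, max(lengths(token_seqs)))

  records <- vector("list", n)
  for (i in seq_len(n)) {
    img <- read_png(manifest$image_path[i])
    feats <- featurize(img, backbone)
    fpath <- file.path(feat_dir, paste0(mols[[i]]$id, ".rds"))
    saveRDS(feats, fpath)
    records[[i]] <- list(
      molecule_id = mols[[i]]$id,
      image_path = manifest$image_path[i],
      feature_path = fpath,
      features = feats,
      text = texts[i],
      target = encode_indices(token_seqs[[i]], vocab, pad_length))
  }
  labels <- data.frame(
    molecule_id = vapply(mols, `[[`, "", "id"),
    representation = representation,
    text = texts,
    tokens = vapply(token_seqs, paste, "", collapse = " "),
    stringsAsFactors = FALSE)
  utils::write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_vocabulary(vocab, file.path(out_dir, "vocabulary.json"))
  write_manifest(manifest, file.path(out_dir, "images.tsv"))
  ds <- structure(list(records = records,
                       split = ifelse(is_test, "test", "train"),
                       vocab = vocab, pad_length = pad_length,
                       representation = representation,
                       base_seed = as.integer(base_seed),
                       backbone_seed = backbone$seed,
                       out_dir = out_dir), class = "ocsr_dataset")
  jsonlite::write_json(list(
    representation = representation, base_seed = base_seed,
    backbone_seed = backbone$seed, pad_length = pad_length,
    n = n, split = ds$split,
    molecule_id = vapply(records, `[[`, "", "molecule_id"),
    image_path = vapply(records, `[[`, "", "image_path"),
    feature_path = vapply(records, `[[`, "", "feature_path")
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  ds
}

#' Load a packaged dataset from its output directory
#'
#' Reconstructs the `ocsr_dataset` written by [package_dataset()] from
#' `manifest.json`, `vocabulary.json`, `labels.tsv` and the per-sample
#' feature files.
#'
#' @param out_dir directory previously given to [package_dataset()]
#' @return an `ocsr_dataset`
#' @export
load_dataset <- function(out_dir) {
  mf <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                            simplifyVector = TRUE)
  vocab <- read_vocabulary(file.path(out_dir, "vocabulary.json"))
  labels <- utils::read.delim(file.path(out_dir, "labels.tsv"),
                              stringsAsFactors = FALSE)
  records <- vector("list", mf$n)
  for (i in seq_len(mf$n)) {
    toks <- strsplit(labels$tokens[i], " ", fixed = TRUE)[[1]]
    records[[i]] <- list(
      molecule_id = mf$molecule_id[i],
      image_path = mf$image_path[i],
      feature_path = mf$feature_path[i],
      features = readRDS(mf$feature_path[i]),
      text = labels$text[i],
      target = encode_indices(toks, vocab, mf$pad_length))
  }
  structure(list(records = records, split = mf$split, vocab = vocab,
                 pad_length = mf$pad_length,
                 representation = mf$representation,
                 base_seed = as.integer(mf$base_seed),
                 backbone_seed = as.integer(mf$backbone_seed),
                 out_dir = out_dir), class = "ocsr_dataset")
}

#' @export
print.ocsr_dataset <- function(x, ...) {
  cat(sprintf("<ocsr_dataset> %d records (%d train / %d test), %s, vocab %d\n",
              length(x$records), sum(x$split == "train"),
              sum(x$split == "test"), x$representation, x$vocab$size))
  invisible(x)
}

#' Subset dataset records by split
#' @param ds an `ocsr_dataset`
#' @param split "train" or "test"
#' @return list of sample records
#' @export
dataset_split <- function(ds, split = c("train", "test")) {
  split <- match.arg(split)
  ds$records[ds$split == split]
}

#' Deterministic epoch-salted batches
#'
#' Every record appears exactly once per epoch; the final short batch is
#' emitted; the permutation is a deterministic function of
#' `(shuffle_seed, epoch)` and differs between epochs.
#'
#' @param samples list of sample records (with `features`, `target`)
#' @param batch_size batch size >= 1
#' @param shuffle_seed integer
#' @param epoch epoch number (salts the shuffle)
#' @return list of batches: each `list(features, targets, idx)` with
#'   `features` a (B*L) x D matrix (rows sample-major) and `targets` a B x T
#'   index matrix
#' @export
batches <- function(samples, batch_size, shuffle_seed = 1L, epoch = 1L) {
  stopifnot(batch_size >= 1L, length(samples) >= 1L)
  n <- length(samples)
  ord <- .with_seed(shuffle_seed + epoch, sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    idx <- ord[s:min(s + batch_size - 1L, n)]
    list(
      features = do.call(rbind, lapply(samples[idx], `[[`, "features")),
      targets = do.call(rbind, lapply(samples[idx],
                                      function(x) as.integer(x$target))),
      idx = idx)
  })
}
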