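# 2D depiction: layout coordinates, one seeded random rotation per molecule,
# rasterization to a fixed-size RGB bitmap, and batch rendering with a
# manifest. Rotation is applied to the layout coordinates about their
# centroid BEFORE rasterization, so no interpolation artifacts or clipped
# corners arise, and scaling is radius-based so a rotation never changes
# whether the drawing fits.

#' Rendering specification
#'
#' @param canvas_px canvas edge length in pixels (default 299, the canvas
#'   used to match common CNN backbones)
#' @param rotation_rad rotation angle in radians, in [0, 2*pi)
#' @param seed integer seed this spec was derived from
#' @return object of class `ocsr_render_spec`
#' @export
render_spec <- function(canvas_px = 299L, rotation_rad = 0, seed = 0L) {
  stopifnot(canvas_px > 0L, rotation_rad >= 0, rotation_rad < 2 * pi)
  structure(list(canvas_px = as.integer(canvas_px),
                 rotation_rad = rotation_rad,
                 seed = as.integer(seed),
                 channels = 3L, background = 255L),
            class = "ocsr_render_spec")
}

#' Draw a rotation angle from a seed
#'
#' Deterministic function of the seed, uniform over [0, 2*pi) across seeds.
#' The global RNG state is left untouched.
#'
#' @param seed integer seed
#' @return angle in radians
#' @export
random_rotation <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  stats::runif(1) * 2 * pi
}

# ---- layout ---------------------------------------------------------------

# Zig-zag tree layout with 120-degree branching for acyclic molecules;
# Kamada-Kawai (igraph, deterministic circular start) for cyclic ones, which
# reproduces ring polygons well at this scale.
.layout_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1L) return(matrix(0, 1L, 2L))
  if (ring_count(mol) == 0L && fragment_count(mol) == 1L) {
    return(.layout_tree(mol))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  start <- igraph::layout_in_circle(g)
  igraph::layout_with_kk(g, coords = start, maxiter = 500L)
}

.layout_tree <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .adjacency(mol)
  coords <- matrix(NA_real_, n, 2L)
  deg <- vapply(seq_len(n), function(i) length(adj[[i]]$nbr), 0L)
  root <- which(deg == min(deg))[1]
  coords[root, ] <- c(0, 0)
  # each atom extends from its parent at +/-30 degrees off horizontal,
  # alternating with depth; extra branches fan out
  place <- function(v, parent, incoming, depth) {
    kids <- setdiff(adj[[v]]$nbr, parent)
    base <- if (depth %% 2L == 0L) pi / 6 else -pi / 6
    angles <- if (length(kids) <= 1L) base
              else seq(base + pi / 3, base - pi / 3, length.out = length(kids))
    for (ki in seq_along(kids)) {
      w <- kids[ki]
      ang <- angles[ki]
      coords[w, ] <<- coords[v, ] + c(cos(ang), sin(ang))
      place(w, v, ang, depth + 1L)
    }
  }
  place(root, NA_integer_, 0, 0L)
  coords
}

# ---- tiny bitmap font for atom labels -------------------------------------

.ocsr_font <- list(
  N = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  S = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  P = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  F = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  I = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
  B = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  C = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  H = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  e = c(".....", ".....", ".###.", "#...#", "#####", "#....", ".###."),
  l = c("##...", ".#...", ".#...", ".#...", ".#...", ".#...", "###.."),
  r = c(".....", ".....", "#.##.", "##..#", "#....", "#....", "#....")
)

.glyph_matrix <- function(ch) {
  rows <- .ocsr_font[[ch]]
  do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
}

# ---- rasterization --------------------------------------------------------

.stamp_black <- function(img, xs, ys, half = 1L) {
  cp <- dim(img)[1]
  for (dx in -half:half) for (dy in -half:half) {
    xx <- round(xs) + dx; yy <- round(ys) + dy
    ok <- xx >= 1L & xx <= cp & yy >= 1L & yy <= cp
    if (any(ok)) {
      for (ch in 1:3) img[cbind(yy[ok], xx[ok], ch)] <- 0L
    }
  }
  img
}

.draw_segment <- function(img, p0, p1, half = 1L) {
  len <- sqrt(sum((p1 - p0)^2))
  nsteps <- max(2L, ceiling(len * 2))
  t <- seq(0, 1, length.out = nsteps)
  .stamp_black(img, p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]), half)
}

.draw_label <- function(img, center, text, scale = 2L) {
  cp <- dim(img)[1]
  glyphs <- lapply(strsplit(text, "")[[1]], .glyph_matrix)
  wid <- sum(vapply(glyphs, ncol, 0L)) * scale + (length(glyphs) - 1L) * scale
  hei <- 7L * scale
  x0 <- round(center[1] - wid / 2); y0 <- round(center[2] - hei / 2)
  # clear a background patch so bond lines do not strike through the label
  xs <- max(1L, x0 - scale):min(cp, x0 + wid + scale)
  ys <- max(1L, y0 - scale):min(cp, y0 + hei + scale)
  img[ys, xs, ] <- 255L
  cx <- x0
  for (g in glyphs) {
    for (gy in seq_len(nrow(g))) for (gx in seq_len(ncol(g))) {
      if (g[gy, gx]) {
        px <- cx + (gx - 1L) * scale; py <- y0 + (gy - 1L) * scale
        xr <- px:(px + scale - 1L); yr <- py:(py + scale - 1L)
        ok_x <- xr >= 1L & xr <= cp; ok_y <- yr >= 1L & yr <= cp
        if (any(ok_x) && any(ok_y)) img[yr[ok_y], xr[ok_x], ] <- 0L
      }
    }
    cx <- cx + (ncol(g) + 1L) * scale
  }
  img
}

.atom_label_text <- function(mol, i) {
  el <- mol$atoms$element[i]
  if (el == "C" && mol$atoms$charge[i] == 0L) return(NULL)  # skeletal carbon
  h <- mol$atoms$hcount[i]
  paste0(el, if (h >= 1L) "H" else "")
}

#' Render a molecule to a fixed-size bitmap
#'
#' Computes 2D layout coordinates, rotates them by `spec$rotation_rad` about
#' their centroid, scales radius-based into the canvas with a margin, and
#' draws bonds (parallel lines for double/triple) and heteroatom labels.
#' Bit-identical output for identical (molecule, spec).
#'
#' @param mol an `ocsr_mol`, `ocsr_molrec`, or SMILES string
#' @param spec an [render_spec()]
#' @param molecule_id identifier stored on the image
#' @return object of class `ocsr_image`: list(pixels, molecule_id, spec)
#' @export
render <- function(mol, spec = render_spec(), molecule_id = NULL) {
  if (is.character(mol)) mol <- molecule_record(mol)
  if (inherits(mol, "ocsr_molrec")) {
    if (is.null(molecule_id)) molecule_id <- mol$id
    mol <- mol$mol
  }
  stopifnot(inherits(mol, "ocsr_mol"))
  if (nrow(mol$atoms) == 0L) stop(ocsr_condition("ocsr_render_error",
    "cannot render an empty molecule", molecule_id = molecule_id))
  coords <- tryCatch(.layout_molecule(mol), error = function(e)
    stop(ocsr_condition("ocsr_render_error",
      paste0("layout failed: ", conditionMessage(e)),
      molecule_id = molecule_id)))

  cp <- spec$canvas_px
  centroid <- colMeans(coords)
  rel <- sweep(coords, 2L, centroid)
  th <- spec$rotation_rad
  rot <- rel %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  rmax <- max(sqrt(rowSums(rot^2)), 1e-9)
  margin <- 0.12 * cp
  scl <- (cp / 2 - margin) / rmax
  pts <- sweep(rot * scl, 2L, c(cp / 2, cp / 2), "+")

  img <- array(255L, c(cp, cp, 3L))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      p0 <- pts[mol$bonds$a1[k], ]; p1 <- pts[mol$bonds$a2[k], ]
      dvec <- p1 - p0
      nrm <- sqrt(sum(dvec^2))
      perp <- if (nrm > 0) c(-dvec[2], dvec[1]) / nrm else c(0, 1)
      ord <- mol$bonds$order[k]
      if (mol$bonds$aromatic[k]) {
        img <- .draw_segment(img, p0, p1)
        # short inner stroke marks aromatic bonds
        img <- .draw_segment(img, p0 + perp * 4 + dvec * 0.25,
                             p0 + perp * 4 + dvec * 0.75, half = 0L)
      } else if (ord == 1L) {
        img <- .draw_segment(img, p0, p1)
      } else if (ord == 2L) {
        img <- .draw_segment(img, p0 + perp * 2.2, p1 + perp * 2.2)
        img <- .draw_segment(img, p0 - perp * 2.2, p1 - perp * 2.2)
      } else {
        img <- .draw_segment(img, p0, p1)
        img <- .draw_segment(img, p0 + perp * 3.2, p1 + perp * 3.2)
        img <- .draw_segment(img, p0 - perp * 3.2, p1 - perp * 3.2)
      }
    }
  }
  for (i in seq_len(nrow(mol$atoms))) {
    lab <- .atom_label_text(mol, i)
    if (!is.null(lab)) img <- .draw_label(img, pts[i, ], lab)
  }
  if (all(img == 255L)) stop(ocsr_condition("ocsr_render_error",
    "blank rendering", molecule_id = molecule_id))
  structure(list(pixels = img, molecule_id = molecule_id, spec = spec),
            class = "ocsr_image")
}

#' @export
print.ocsr_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ocsr_image> %dx%dx%d, %s, rotation %.3f rad\n",
              d[1], d[2], d[3],
              if (is.null(x$molecule_id)) "unnamed" else x$molecule_id,
              x$spec$rotation_rad))
  invisible(x)
}

# stable 31-bit hash of a molecule id, for per-molecule rotation seeds
.id_hash <- function(id) {
  h <- 0
  for (b in utf8ToInt(id)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Render a batch of molecules to PNG files with a manifest
#'
#' Each molecule gets rotation seed `(base_seed + stable hash of its id)
#' mod 2^31 - 1`, so re-running with the same `base_seed` reproduces every
#' file byte-identically. Per-molecule render failures are recorded and
#' excluded from the manifest; they never abort the batch.
#'
#' @param mols list of `ocsr_molrec`
#' @param out_dir writable output directory (created if missing)
#' @param base_seed integer
#' @param canvas_px canvas size (default 299)
#' @return data.frame manifest: molecule_id, image_path, rotation_rad, seed;
#'   attribute "failures" lists failed molecule ids
#' @export
render_dataset <- function(mols, out_dir, base_seed = 1L, canvas_px = 299L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  failures <- character(0)
  for (rec in mols) {
    seed <- (as.numeric(base_seed) + .id_hash(rec$id)) %% 2147483647
    spec <- render_spec(canvas_px, random_rotation(seed), as.integer(seed))
    path <- file.path(out_dir, paste0(rec$id, ".png"))
    ok <- tryCatch({
      img <- render(rec, spec)
      write_png(img$pixels, path)
      TRUE
    }, ocsr_error = function(e) FALSE)
    if (ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = rec$id, image_path = path,
        rotation_rad = spec$rotation_rad, seed = spec$seed,
        stringsAsFactors = FALSE)
    } else {
      failures <- c(failures, rec$id)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = character(0), image_path = character(0),
               rotation_rad = numeric(0), seed = integer(0))
  attr(manifest, "failures") <- failures
  manifest
}

#' Write/read a depiction manifest TSV
#' @param manifest data.frame from [render_dataset()]
#' @param path TSV path
#' @return invisibly `path` / the manifest data.frame
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
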