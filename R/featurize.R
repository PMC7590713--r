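# Image featurizer: contract + small built-in default backbone.
#
# The featurizer contract is: any deterministic function mapping a rendered
# bitmap to a fixed (L x D) grid of spatial features is admissible (a
# pretrained large CNN plugs in here for full-scale runs). The built-in
# default is a frozen, seeded random-projection patch encoder: the image is
# grayscaled, area-downsampled to 64 x 64, cut into an 8 x 8 grid of 8 x 8
# patches (L = 64 locations), and each flattened patch is mapped through a
# fixed random affine map with tanh. Random but frozen filters preserve
# enough spatial information for desk-scale experiments.

#' Construct the default frozen patch backbone
#'
#' @param feature_dim D, channels per spatial location (default 64)
#' @param seed seed for the frozen random projection (default 4242)
#' @param grid locations per side (default 8, so L = 64)
#' @param pool pooled image edge in pixels (default 64)
#' @return object of class `ocsr_backbone` (callable via [featurize()])
#' @export
default_backbone <- function(feature_dim = 64L, seed = 4242L, grid = 8L,
                             pool = 64L) {
  patch_px <- pool %/% grid
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w <- matrix(stats::rnorm(patch_px^2 * feature_dim, sd = 1 / patch_px),
              nrow = patch_px^2, ncol = feature_dim)
  b <- stats::rnorm(feature_dim, sd = 0.1)
  structure(list(w = w, b = b, grid = as.integer(grid),
                 pool = as.integer(pool), feature_dim = as.integer(feature_dim),
                 n_locations = as.integer(grid^2), seed = as.integer(seed)),
            class = "ocsr_backbone")
}

# area-average downsample of a [h, w] matrix to [pool, pool]
.pool_gray <- function(gray, pool) {
  h <- nrow(gray); w <- ncol(gray)
  gy <- ceiling(seq_len(h) * pool / h)
  gx <- ceiling(seq_len(w) * pool / w)
  s <- rowsum(gray, gy)              # pool x w
  s <- t(rowsum(t(s), gx))           # pool x pool
  s / outer(tabulate(gy, pool), tabulate(gx, pool))
}

#' Convert a structure image into a spatial feature grid
#'
#' @param image an `ocsr_image` or an integer pixel array (h, w, 3)
#' @param backbone an `ocsr_backbone` (default: [default_backbone()])
#' @return numeric matrix L x D of spatial features
#' @export
featurize <- function(image, backbone = default_backbone()) {
  px <- if (inherits(image, "ocsr_image")) image$pixels else image
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L) stop(ocsr_condition(
    "ocsr_contract_violation", "featurize expects an (h, w, 3) pixel array"))
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / (3 * 255)
  gray <- 1 - gray                      # ink = 1, background = 0
  pooled <- .pool_gray(gray, backbone$pool)
  pp <- backbone$pool %/% backbone$grid
  feats <- matrix(0, backbone$n_locations, backbone$feature_dim)
  loc <- 0L
  for (gy in seq_len(backbone$grid)) {
    for (gx in seq_len(backbone$grid)) {
      loc <- loc + 1L
      patch <- pooled[((gy - 1L) * pp + 1L):(gy * pp),
                      ((gx - 1L) * pp + 1L):(gx * pp)]
      feats[loc, ] <- tanh(as.vector(patch) %*% backbone$w + backbone$b)
    }
  }
  feats
}
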