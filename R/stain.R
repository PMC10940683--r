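# Stain separation and normalization for HE-stained patches.
#
# Working space is optical density (Beer-Lambert): OD = -log10(I / I0) with
# I0 = 255, in which pixel OD vectors are nonnegative linear combinations of
# the two stain color vectors (hematoxylin, eosin). The stain basis is
# estimated by a 2-atom sparse nonnegative matrix factorization of tissue
# OD pixels; normalization refits concentrations under the source basis,
# matches per-stain 99th-percentile concentrations to the target's and
# recomposes under the target basis.

# Reference H&E optical-density vectors (Ruifrok-Johnston), unit-normalised;
# used to seed the NMF and as the default synthetic staining basis.
he_reference_basis <- function() {
  W <- cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  sweep(W, 2L, sqrt(colSums(W^2)), "/")
}

assert_rgb8 <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L)
    stop(what, " must be an (H, W, 3) RGB array")
  invisible(TRUE)
}

#' Convert an RGB image to optical density
#'
#' `OD = -log10(I / 255)` per channel, with intensities clipped at 1 to
#' avoid `log(0)`. White (255) maps to OD 0.
#'
#' @param img numeric `(H, W, 3)` array of 8-bit intensities (0..255).
#' @return numeric `(H, W, 3)` array of optical densities (all `>= 0`).
#' @export
rgb_to_od <- function(img) {
  assert_rgb8(img)
  -log10(pmax(img, 1) / 255)
}

#' Convert optical density back to 8-bit RGB
#'
#' Inverse of [rgb_to_od()] up to rounding.
#'
#' @param od numeric `(H, W, 3)` array of optical densities.
#' @return numeric `(H, W, 3)` array of rounded intensities in 0..255.
#' @export
od_to_rgb <- function(od) {
  assert_rgb8(od, "od")
  pmin(pmax(round(255 * 10^(-od)), 0), 255)
}

# vectorised nonnegative least squares for a 3x2 basis: per-pixel
# concentrations minimising ||W h - v||^2, h >= 0 (exact over the 3 active
# sets of a 2-variable problem)
nnls_conc <- function(W, V) {
  G <- crossprod(W)            # 2x2
  B <- crossprod(W, V)         # 2xn
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  h1 <- (G[2, 2] * B[1, ] - G[1, 2] * B[2, ]) / det
  h2 <- (G[1, 1] * B[2, ] - G[1, 2] * B[1, ]) / det
  ok <- h1 >= 0 & h2 >= 0
  # single-stain fallbacks, picked by residual
  a1 <- pmax(B[1, ] / G[1, 1], 0)
  a2 <- pmax(B[2, ] / G[2, 2], 0)
  r1 <- -2 * a1 * B[1, ] + a1^2 * G[1, 1]
  r2 <- -2 * a2 * B[2, ] + a2^2 * G[2, 2]
  use1 <- !ok & (r1 <= r2)
  use2 <- !ok & (r1 > r2)
  h1[use1] <- a1[use1]; h2[use1] <- 0
  h1[use2] <- 0; h2[use2] <- a2[use2]
  rbind(h1, h2)
}

#' Estimate a two-stain basis by sparse NMF on optical-density pixels
#'
#' Tissue pixels (OD norm above `od_threshold`) are factorised as
#' `V ~ W %*% H` with nonnegative `W` (3 x 2) and sparse nonnegative
#' concentrations `H`, by multiplicative updates with an L1 penalty on `H`.
#' Columns are unit-normalised and ordered hematoxylin first (larger red-OD
#' component). The returned basis also records the 99th-percentile
#' concentration of each stain in the fitted image, which anchors the
#' rescaling step of [normalize_stain()].
#'
#' @param img numeric `(H, W, 3)` RGB array (0..255).
#' @param sparsity L1 penalty weight on the concentrations.
#' @param seed seed for pixel subsampling.
#' @param od_threshold minimum OD Euclidean norm for a pixel to count as
#'   tissue.
#' @param max_pixels subsample size for the factorisation.
#' @param n_iter multiplicative-update iterations.
#' @return an object of class `stain_basis`: list with `W` (3 x 2,
#'   unit-norm nonnegative columns), `p99` (per-stain concentration scale)
#'   and `degenerate` flag.
#' @export
estimate_stain_basis <- function(img, sparsity = 0.1, seed = 1L,
                                 od_threshold = 0.15, max_pixels = 2000L,
                                 n_iter = 300L) {
  assert_rgb8(img)
  od <- rgb_to_od(img)
  V <- t(matrix(od, ncol = 3L))                     # 3 x npix
  tissue <- colSums(V^2) > od_threshold^2
  if (sum(tissue) < 1000L)
    stop("insufficient tissue: only ", sum(tissue),
         " pixels above the OD threshold (need >= 1000)")
  V <- V[, tissue, drop = FALSE]
  if (ncol(V) > max_pixels) {
    set.seed(seed)
    V <- V[, sample.int(ncol(V), max_pixels), drop = FALSE]
  }
  W <- he_reference_basis()
  eps <- 1e-12
  H <- pmax(nnls_conc(W, V), eps)
  for (it in seq_len(n_iter)) {
    H <- H * crossprod(W, V) / (crossprod(W) %*% H + sparsity + eps)
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    W <- sweep(W, 2L, pmax(sqrt(colSums(W^2)), eps), "/")
  }
  # debias: the L1 penalty shrinks concentrations and tilts the dictionary
  # to compensate; polish directions with a few unpenalized alternations
  for (it in seq_len(max(20L, n_iter %/% 10L))) {
    H <- pmax(nnls_conc(W, V), eps)
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    W <- sweep(W, 2L, pmax(sqrt(colSums(W^2)), eps), "/")
  }
  ord <- order(W[1L, ], decreasing = TRUE)          # hematoxylin: high red-OD
  W <- W[, ord, drop = FALSE]
  H <- nnls_conc(W, V)
  p99 <- apply(H, 1L, stats::quantile, probs = 0.99, names = FALSE)
  cosang <- sum(W[, 1L] * W[, 2L])
  degenerate <- cosang > 0.98 || min(p99) < 0.05 * max(p99)
  if (degenerate)
    warning("degenerate stain basis: second atom is nearly collinear or ",
            "unused (single-stain image?)")
  structure(list(W = W, p99 = p99, degenerate = degenerate),
            class = "stain_basis")
}

#' Normalize an image from a source stain basis to a target basis
#'
#' Concentrations are fitted per pixel under the source basis by nonnegative
#' least squares, rescaled so each stain's 99th-percentile concentration
#' matches the target's, and recomposed under the target basis. Background
#' (near-white) pixels have near-zero concentrations and are preserved.
#'
#' @param img numeric `(H, W, 3)` RGB array (0..255).
#' @param source,target `stain_basis` objects ([estimate_stain_basis()]).
#' @return normalized `(H, W, 3)` RGB array.
#' @export
normalize_stain <- function(img, source, target) {
  assert_rgb8(img)
  stopifnot(inherits(source, "stain_basis"), inherits(target, "stain_basis"))
  d <- dim(img)
  V <- t(matrix(rgb_to_od(img), ncol = 3L))
  H <- nnls_conc(source$W, V)
  scale <- ifelse(source$p99 > 1e-8, target$p99 / source$p99, 1)
  od_new <- target$W %*% (H * scale)
  od_to_rgb(array(t(od_new), d))
}

#' Mean-OD color spread of a set of images
#'
#' Sum over channels of the across-image variance of mean optical density;
#' a scalar summary of inter-image color variation used to quantify the
#' effect of stain normalization.
#'
#' @param imgs list of `(H, W, 3)` RGB arrays.
#' @return nonnegative scalar.
#' @export
od_color_spread <- function(imgs) {
  mo <- vapply(imgs, function(im) apply(rgb_to_od(im), 3L, mean), numeric(3L))
  sum(apply(mo, 1L, stats::var))
}
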