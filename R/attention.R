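# Dimension-information-embedding attention (DIEA) and the coordinate
# attention (CA) baseline, as pure tensor-to-tensor computations on
# (C, H, W) feature maps.
#
# DIEA pipeline: strip average + strip max pooling along both spatial axes
# -> concatenation into two 1-D descriptors of length H+W -> squeeze-style
# 1x1-conv bottleneck with BN and hard-swish -> split into two directional
# embeddings -> per-channel outer product (the (H+W)x(H+W) embedding map)
# -> strided 3x3 downsampling convolution -> sigmoid gate multiplied into
# the input.

#' DIEA configuration
#'
#' @param channels number of input channels C.
#' @param reduction channel reduction ratio r of the squeeze bottleneck; the
#'   mid channel count is `max(min_mid_channels, floor(channels / reduction))`.
#' @param min_mid_channels lower floor on the bottleneck width.
#' @param pool_mode `"AP_MP"` (published operator: average + max strips),
#'   `"AP_AP"` or `"MP_MP"` (ablation variants replacing both branches by
#'   average resp. max pooling).
#' @param downsample_grouping grouping of the 3x3/stride-2 recovery
#'   convolution: `"depthwise"` (default), `"full"`, or an integer number of
#'   groups.
#' @param bn_eps,bn_momentum batch-normalisation constants.
#' @param gate_resize `"require_square"` (error on H != W) or `"bilinear"`
#'   (resize the gate to H x W).
#' @return a `diea_config` list.
#' @export
diea_config <- function(channels, reduction = 32L, min_mid_channels = 8L,
                        pool_mode = c("AP_MP", "AP_AP", "MP_MP"),
                        downsample_grouping = "depthwise",
                        bn_eps = 1e-5, bn_momentum = 0.1,
                        gate_resize = c("require_square", "bilinear")) {
  pool_mode <- match.arg(pool_mode)
  gate_resize <- match.arg(gate_resize)
  mid <- max(as.integer(min_mid_channels), channels %/% as.integer(reduction))
  if (mid < 1L)
    stop("configuration error: floor(channels / reduction) < 1 and no usable ",
         "min_mid_channels floor")
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 min_mid_channels = as.integer(min_mid_channels),
                 mid_channels = as.integer(mid),
                 pool_mode = pool_mode,
                 downsample_grouping = downsample_grouping,
                 bn_eps = bn_eps, bn_momentum = bn_momentum,
                 gate_resize = gate_resize),
            class = "diea_config")
}

downsample_groups <- function(cfg) {
  g <- cfg$downsample_grouping
  if (identical(g, "depthwise")) return(cfg$channels)
  if (identical(g, "full")) return(1L)
  g <- as.integer(g)
  if (is.na(g) || g < 1L || cfg$channels %% g != 0L)
    stop("downsample_grouping must be 'depthwise', 'full' or a divisor of C")
  g
}

#' Initialise DIEA weights
#'
#' 1x1 convolutions are bias-free (BN follows); the recovery convolution
#' carries a bias. Convolutions use Kaiming-uniform initialisation, BN
#' gamma = 1, beta = 0.
#'
#' @param cfg a [diea_config()].
#' @param seed optional integer seed.
#' @return named list of weight arrays and BN states.
#' @export
diea_init <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- cfg$channels; Cm <- cfg$mid_channels
  g <- downsample_groups(cfg)
  list(W1 = kaiming_uniform(c(Cm, C, 1L, 1L), C),
       bn1 = bn_init(Cm),
       W2 = kaiming_uniform(c(C, Cm, 1L, 1L), Cm),
       bn2 = bn_init(C),
       W3 = kaiming_uniform(c(C, Cm, 1L, 1L), Cm),
       bn3 = bn_init(C),
       Wd = kaiming_uniform(c(C, C %/% g, 3L, 3L), (C %/% g) * 9L),
       bd = rep(0, C))
}

w1x1 <- function(w) matrix(w, nrow = dim(w)[1L])  # (cout, cin, 1, 1) -> matrix

#' Strip average pooling
#'
#' Pools each channel along full rows and full columns: `a_h[c, h]` is the
#' mean of row `h`, `a_w[c, w]` the mean of column `w`.
#'
#' @param x numeric `(C, H, W)` array.
#' @return list with `a_h` (C x H) and `a_w` (C x W) matrices.
#' @examples
#' x <- array(c(1, 5, 3, 7), c(1, 2, 2))
#' strip_avg_pool(x)
#' @export
strip_avg_pool <- function(x) {
  assert_feature_map(x)
  d <- dim(x)
  list(a_h = rowSums(x, dims = 2L) / d[3L],
       a_w = colSums(aperm(x, c(2L, 1L, 3L))) / d[2L])
}

#' Strip max pooling
#'
#' `m_h[c, h]` is the maximum of row `h` of channel `c`; `m_w[c, w]` the
#' maximum of column `w`.
#'
#' @inheritParams strip_avg_pool
#' @return list with `m_h` (C x H) and `m_w` (C x W) matrices.
#' @export
strip_max_pool <- function(x) {
  assert_feature_map(x)
  list(m_h = apply(x, c(1L, 2L), max),
       m_w = apply(x, c(1L, 3L), max))
}

#' Concatenate strip descriptors into length-(H+W) descriptors
#'
#' Splices the horizontal descriptor with the transposed vertical descriptor
#' into one 1-D descriptor per channel, for the average branch and the max
#' branch alike.
#'
#' @param sd list with `a_h`, `a_w`, `m_h`, `m_w` (as produced by the strip
#'   pooling functions; branch names fixed).
#' @return list with `a` and `m`, both C x (H+W) matrices.
#' @export
concat_strips <- function(sd) {
  cs <- vapply(sd[c("a_h", "a_w", "m_h", "m_w")], nrow, integer(1))
  if (length(unique(cs)) != 1L)
    stop("mismatched channel counts across strip descriptors")
  if (ncol(sd$a_h) != ncol(sd$m_h) || ncol(sd$a_w) != ncol(sd$m_w))
    stop("mismatched strip lengths between average and max branches")
  list(a = cbind(sd$a_h, sd$a_w), m = cbind(sd$m_h, sd$m_w))
}

#' Fuse the concatenated descriptors through the squeeze bottleneck
#'
#' Splices `a` and `m` into one length-2(H+W) sequence per channel and applies
#' the 1x1 squeeze convolution, batch normalisation and hard-swish.
#'
#' @param cd list with `a` and `m` (from [concat_strips()]).
#' @param weights DIEA weights ([diea_init()]).
#' @param cfg a [diea_config()].
#' @param training use batch statistics (`TRUE`) or running statistics.
#' @return `(C/r) x (2H+2W)` matrix of fused features.
#' @export
fuse_descriptors <- function(cd, weights, cfg, training = FALSE) {
  tm <- cbind(cd$a, cd$m)
  u <- w1x1(weights$W1) %*% tm
  h_swish(bn_forward(u, weights$bn1, training, cfg$bn_eps)$y)
}

#' Split the fused descriptor and expand back to C channels
#'
#' The first H+W positions feed the average-branch expansion `F2`, the last
#' H+W positions are transposed and feed the max-branch expansion `F3`; both
#' are followed by BN. Returns the two directional embeddings with shapes
#' C x (H+W) x 1 and C x 1 x (H+W).
#'
#' @param h fused `(C/r) x (2H+2W)` matrix (from [fuse_descriptors()]).
#' @param weights,cfg,training as in [fuse_descriptors()].
#' @return list with `h_a` (C x (H+W) x 1) and `h_m` (C x 1 x (H+W)) arrays.
#' @export
split_and_expand <- function(h, weights, cfg, training = FALSE) {
  L <- ncol(h)
  if (L %% 2L != 0L)
    stop("fused descriptor length must be exactly 2(H + W)")
  S <- L %/% 2L
  C <- nrow(weights$W2)
  va <- bn_forward(w1x1(weights$W2) %*% h[, seq_len(S), drop = FALSE],
                   weights$bn2, training, cfg$bn_eps)$y
  vm <- bn_forward(w1x1(weights$W3) %*% h[, S + seq_len(S), drop = FALSE],
                   weights$bn3, training, cfg$bn_eps)$y
  list(h_a = array(va, c(C, S, 1L)),
       h_m = array(vm, c(C, 1L, S)))
}

#' Per-channel outer product of the directional embeddings
#'
#' `h_am[c, p, q] = h_a[c, p, 1] * h_m[c, 1, q]`; every channel slice has
#' rank at most one. The four quadrants carry the four same/cross-dimension
#' interactions of the average and max strip descriptors.
#'
#' @param de list with `h_a` (C x S x 1) and `h_m` (C x 1 x S).
#' @return numeric `(C, S, S)` array.
#' @export
outer_embed <- function(de) {
  da <- dim(de$h_a); dm <- dim(de$h_m)
  if (length(da) != 3L || length(dm) != 3L || da[3L] != 1L || dm[2L] != 1L ||
      da[1L] != dm[1L] || da[2L] != dm[3L])
    stop("directional embeddings must have shapes C x S x 1 and C x 1 x S")
  C <- da[1L]; S <- da[2L]
  ha <- matrix(de$h_a, C, S); hm <- matrix(de$h_m, C, S)
  array(ha, c(C, S, S)) * aperm(array(hm, c(C, S, S)), c(1L, 3L, 2L))
}

#' Downsample the embedding map to a gate and apply it
#'
#' A 3x3, stride-2, padding-1 convolution (depthwise by default) maps the
#' (H+W) x (H+W) embedding map to H x W when the input is square; the sigmoid
#' of the result gates the input multiplicatively.
#'
#' @param x input `(C, H, W)` feature map.
#' @param h_am embedding map `(C, H+W, H+W)`.
#' @param weights,cfg as in [fuse_descriptors()].
#' @return list with `y` (gated features) and `g` (the gate, entries in (0,1)).
#' @export
gate_and_apply <- function(x, h_am, weights, cfg) {
  assert_feature_map(x)
  d <- dim(x); H <- d[2L]; W <- d[3L]
  if (H != W && cfg$gate_resize == "require_square")
    stop("non-square input (H = ", H, ", W = ", W, ") requires gate_resize = ",
         "'bilinear'; gate_resize = 'require_square' is set")
  z <- conv2d(h_am, weights$Wd, weights$bd, stride = 2L, pad = 1L,
              groups = downsample_groups(cfg))
  if (!identical(dim(z)[2:3], c(H, W))) {
    zr <- array(0, c(d[1L], H, W))
    for (c_ in seq_len(d[1L])) zr[c_, , ] <- bilinear_resize(z[c_, , ], H, W)
    z <- zr
  }
  g <- sigmoid_(z)
  list(y = x * g, g = g)
}

#' DIEA forward pass
#'
#' Applies the full attention operator to a single feature map and returns a
#' map of identical shape. `pool_mode` selects the published average+max
#' combination or the all-average / all-max ablation variants.
#'
#' @param x numeric `(C, H, W)` array with `C == cfg$channels`.
#' @param cfg a [diea_config()].
#' @param weights weights from [diea_init()].
#' @param training use batch (`TRUE`) or running BN statistics.
#' @param with_gate also return the attention gate.
#' @return the gated feature map, or (with `with_gate`) a list `y`, `g`.
#' @export
diea_forward <- function(x, cfg, weights, training = FALSE, with_gate = FALSE) {
  assert_feature_map(x)
  if (dim(x)[1L] != cfg$channels)
    stop("input has ", dim(x)[1L], " channels but cfg$channels = ", cfg$channels)
  ap <- strip_avg_pool(x)
  mp <- strip_max_pool(x)
  sd <- switch(cfg$pool_mode,
    AP_MP = list(a_h = ap$a_h, a_w = ap$a_w, m_h = mp$m_h, m_w = mp$m_w),
    AP_AP = list(a_h = ap$a_h, a_w = ap$a_w, m_h = ap$a_h, m_w = ap$a_w),
    MP_MP = list(a_h = mp$m_h, a_w = mp$m_w, m_h = mp$m_h, m_w = mp$m_w))
  cd <- concat_strips(sd)
  h <- fuse_descriptors(cd, weights, cfg, training)
  de <- split_and_expand(h, weights, cfg, training)
  ga <- gate_and_apply(x, outer_embed(de), weights, cfg)
  if (with_gate) ga else ga$y
}

#' Initialise coordinate-attention weights
#'
#' The CA baseline shares the squeeze bottleneck (1x1 conv + BN + hard-swish
#' on the concatenated average strips) and expands with two per-direction
#' 1x1 convolutions followed by sigmoids.
#'
#' @inheritParams diea_init
#' @export
ca_init <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- cfg$channels; Cm <- cfg$mid_channels
  list(W1 = kaiming_uniform(c(Cm, C, 1L, 1L), C),
       bn1 = bn_init(Cm),
       Wh = kaiming_uniform(c(C, Cm, 1L, 1L), Cm),
       Ww = kaiming_uniform(c(C, Cm, 1L, 1L), Cm))
}

#' Coordinate attention forward pass
#'
#' Average strip pooling in both directions, a shared bottleneck, and two
#' directional sigmoid gates whose product gates the input:
#' `g[c, i, j] = g_h[c, i] * g_w[c, j]`.
#'
#' @inheritParams diea_forward
#' @export
ca_forward <- function(x, cfg, weights, training = FALSE, with_gate = FALSE) {
  assert_feature_map(x)
  d <- dim(x); H <- d[2L]; W <- d[3L]
  ap <- strip_avg_pool(x)
  u <- w1x1(weights$W1) %*% cbind(ap$a_h, ap$a_w)
  h <- h_swish(bn_forward(u, weights$bn1, training, cfg$bn_eps)$y)
  g_h <- sigmoid_(w1x1(weights$Wh) %*% h[, seq_len(H), drop = FALSE])
  g_w <- sigmoid_(w1x1(weights$Ww) %*% h[, H + seq_len(W), drop = FALSE])
  g <- array(g_h, c(d[1L], H, W)) *
    aperm(array(g_w, c(d[1L], W, H)), c(1L, 3L, 2L))
  if (with_gate) list(y = x * g, g = g) else x * g
}

# trainable parameter counts, used by the backbone budget accountant
diea_param_count <- function(cfg) {
  C <- cfg$channels; Cm <- cfg$mid_channels
  g <- downsample_groups(cfg)
  Cm * C + 2L * Cm +          # F1 + BN1
    2L * (C * Cm + 2L * C) +  # F2 + BN2, F3 + BN3
    C * (C %/% g) * 9L + C    # F-down (with bias)
}

ca_param_count <- function(cfg) {
  C <- cfg$channels; Cm <- cfg$mid_channels
  Cm * C + 2L * Cm + 2L * C * Cm
}

# MAC counts at a given (H, W), conv + linear convention
diea_mac_count <- function(cfg, H, W) {
  C <- cfg$channels; Cm <- cfg$mid_channels; S <- H + W
  g <- downsample_groups(cfg)
  Cm * C * 2 * S +            # F1 over 2(H+W) positions
    2 * C * Cm * S +          # F2, F3
    C * (C %/% g) * 9 * H * W # F-down (stride 2 over (2S)^2 -> H x W)
}

ca_mac_count <- function(cfg, H, W) {
  C <- cfg$channels; Cm <- cfg$mid_channels; S <- H + W
  Cm * C * S + C * Cm * S
}
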