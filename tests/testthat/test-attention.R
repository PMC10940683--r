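# The DIEA operator: strip pooling, descriptor fusion, directional
# embeddings, outer-product recovery and gating, against worked examples
# and independent loop oracles.

test_that("strip pooling matches direct arithmetic on a worked example", {
  x <- array(0, c(1, 2, 2))
  x[1, 1, ] <- c(1, 3); x[1, 2, ] <- c(5, 7)
  ap <- strip_avg_pool(x)
  mp <- strip_max_pool(x)
  expect_equal(drop(ap$a_h), c(2, 6))
  expect_equal(drop(ap$a_w), c(3, 5))
  expect_equal(drop(mp$m_h), c(3, 7))
  expect_equal(drop(mp$m_w), c(5, 7))
})

test_that("strip pooling of a constant map is constant", {
  x <- array(4.2, c(3, 5, 7))
  ap <- strip_avg_pool(x); mp <- strip_max_pool(x)
  expect_true(all(ap$a_h == 4.2) && all(ap$a_w == 4.2))
  expect_true(all(mp$m_h == 4.2) && all(mp$m_w == 4.2))
})

test_that("strip pooling equals brute-force loops on random tensors", {
  set.seed(101)
  for (rep in 1:100) {
    d <- sample(1:8, 3, replace = TRUE)
    x <- rand_tensor(d[1], d[2], d[3])
    ap <- strip_avg_pool(x); lo <- loop_strip_avg(x)
    expect_lt(max(abs(ap$a_h - lo$a_h), abs(ap$a_w - lo$a_w)), 1e-6)
    mp <- strip_max_pool(x); lm <- loop_strip_max(x)
    expect_identical(max(abs(mp$m_h - lm$m_h), abs(mp$m_w - lm$m_w)), 0)
  }
})

test_that("max strips dominate average strips, with equality iff constant", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rand_tensor(4, 6, 5)
    ap <- strip_avg_pool(x); mp <- strip_max_pool(x)
    expect_true(all(mp$m_h >= ap$a_h) && all(mp$m_w >= ap$a_w))
    expect_true(all(mp$m_h > ap$a_h))  # a.s. strict for continuous noise
  }
  xc <- array(1.5, c(2, 3, 3))
  expect_equal(strip_max_pool(xc)$m_h, strip_avg_pool(xc)$a_h)
})

test_that("pooling rejects malformed inputs", {
  expect_error(strip_avg_pool(matrix(1, 2, 2)), "array")
  expect_error(strip_avg_pool(array(c(1, NA), c(1, 1, 2))), "finite")
})

test_that("concatenation splices h- then transposed w-descriptors", {
  sd <- list(a_h = matrix(1:2, 1), a_w = matrix(3, 1),
             m_h = matrix(4:5, 1), m_w = matrix(6, 1))
  cd <- concat_strips(sd)
  expect_equal(drop(cd$a), c(1, 2, 3))
  expect_equal(drop(cd$m), c(4, 5, 6))
  # round trip: splitting at H recovers both branches
  H <- 2
  expect_equal(cd$a[, seq_len(H), drop = FALSE], sd$a_h)
  expect_equal(cd$a[, -seq_len(H), drop = FALSE], sd$a_w)
  sd$m_h <- matrix(1:4, 2)
  expect_error(concat_strips(sd), "channel")
})

test_that("concatenated descriptors have length H + W", {
  x <- rand_tensor(3, 2, 3)
  cd <- concat_strips(c(strip_avg_pool(x), strip_max_pool(x)))
  expect_equal(dim(cd$a), c(3, 5))
  expect_equal(cd$a[, 1:2], strip_avg_pool(x)$a_h)
})

test_that("hard swish matches its closed form", {
  expect_equal(h_swish(0), 0)
  expect_equal(h_swish(3), 3)
  expect_equal(h_swish(-3), 0)
  expect_equal(h_swish(-5), 0)
  expect_equal(h_swish(1), 2 / 3)
  expect_equal(h_swish(10), 10)
})

test_that("fusion bottleneck has the squeeze shape and zero fixed point", {
  cfg <- diea_config(64, reduction = 32, min_mid_channels = 8)
  expect_equal(cfg$mid_channels, 8L)  # floor(64/32) = 2, floored up to 8
  w <- diea_init(cfg, seed = 1)
  cd <- list(a = matrix(0, 64, 16), m = matrix(0, 64, 16))  # H = W = 8
  h <- fuse_descriptors(cd, w, cfg)
  expect_equal(dim(h), c(8L, 32L))
  expect_true(all(h == 0))  # BN(0) = 0 at init stats, h_swish(0) = 0
})

test_that("fusion equals composing squeeze conv, BN and hard swish manually", {
  cfg <- diea_config(16, reduction = 4)
  w <- diea_init(cfg, seed = 3)
  set.seed(9)
  cd <- list(a = matrix(rnorm(16 * 10), 16), m = matrix(rnorm(16 * 10), 16))
  h <- fuse_descriptors(cd, w, cfg)
  u <- matrix(w$W1, nrow = dim(w$W1)[1]) %*% cbind(cd$a, cd$m)
  bn <- (u - w$bn1$running_mean) / sqrt(w$bn1$running_var + cfg$bn_eps) *
    w$bn1$gamma + w$bn1$beta
  expect_lt(max(abs(h - bn * pmin(pmax(bn + 3, 0), 6) / 6)), 1e-6)
})

test_that("split-and-expand produces the two directional embedding shapes", {
  cfg <- diea_config(12, reduction = 4)   # mid = 8
  w <- diea_init(cfg, seed = 2)
  h <- matrix(rnorm(8 * 16), 8)           # H = 3, W = 5 -> 2(H+W) = 16
  de <- split_and_expand(h, w, cfg)
  expect_equal(dim(de$h_a), c(12L, 8L, 1L))
  expect_equal(dim(de$h_m), c(12L, 1L, 8L))
  expect_error(split_and_expand(h[, 1:15], w, cfg), "2\\(H \\+ W\\)")
  z <- split_and_expand(matrix(0, 8, 16), w, cfg)
  expect_true(all(z$h_a == 0) && all(z$h_m == 0))
})

test_that("split-and-expand equals per-position matrix multiplication", {
  cfg <- diea_config(10, reduction = 2)
  w <- diea_init(cfg, seed = 5)
  set.seed(5)
  S <- 7
  h <- matrix(rnorm(cfg$mid_channels * 2 * S), cfg$mid_channels)
  de <- split_and_expand(h, w, cfg)
  W2 <- matrix(w$W2, nrow = 10); W3 <- matrix(w$W3, nrow = 10)
  bnf <- 1 / sqrt(1 + cfg$bn_eps)  # inference BN at initial running stats
  for (p in seq_len(S)) {
    expect_lt(max(abs(de$h_a[, p, 1] - bnf * drop(W2 %*% h[, p]))), 1e-6)
    expect_lt(max(abs(de$h_m[, 1, p] - bnf * drop(W3 %*% h[, S + p]))), 1e-6)
  }
})

test_that("outer embedding is the per-channel outer product", {
  de <- list(h_a = array(c(1, 2), c(1, 2, 1)),
             h_m = array(c(3, 4), c(1, 1, 2)))
  expect_equal(outer_embed(de)[1, , ], matrix(c(3, 6, 4, 8), 2))
  set.seed(11)
  de <- list(h_a = array(rnorm(5 * 6), c(5, 6, 1)),
             h_m = array(rnorm(5 * 6), c(5, 1, 6)))
  h_am <- outer_embed(de)
  expect_identical(h_am, loop_outer(de$h_a, de$h_m))
  expect_lt(max_rank1_residual(h_am), 1e-6)
  expect_error(outer_embed(list(h_a = de$h_a, h_m = array(0, c(5, 1, 4)))),
               "shapes")
})

test_that("gate is bounded in (0,1) and attenuates the input", {
  cfg <- diea_config(6, reduction = 2)
  w <- diea_init(cfg, seed = 8)
  set.seed(8)
  x <- rand_tensor(6, 8, 8)
  de <- split_and_expand(fuse_descriptors(
    concat_strips(c(strip_avg_pool(x), strip_max_pool(x))), w, cfg), w, cfg)
  ga <- gate_and_apply(x, outer_embed(de), w, cfg)
  expect_true(all(ga$g > 0 & ga$g < 1))
  expect_true(all(abs(ga$y) <= abs(x)))
  expect_true(all(sign(ga$y) == sign(x) | x == 0))
  expect_equal(dim(ga$g), dim(x))  # 16x16 embedding -> 8x8 gate
})

test_that("zero downsampling weights give the half gate", {
  cfg <- diea_config(4, reduction = 2)
  w <- diea_init(cfg, seed = 4)
  w$Wd[] <- 0; w$bd[] <- 0
  x <- rand_tensor(4, 6, 6)
  h_am <- array(rnorm(4 * 12 * 12), c(4, 12, 12))
  ga <- gate_and_apply(x, h_am, w, cfg)
  expect_equal(ga$g, array(0.5, dim(x)))
  expect_equal(ga$y, x / 2)
})

test_that("non-square inputs are rejected unless bilinear resize is chosen", {
  cfg <- diea_config(4, reduction = 2)
  w <- diea_init(cfg, seed = 6)
  x <- rand_tensor(4, 4, 6)
  expect_error(diea_forward(x, cfg, w), "gate_resize")
  cfgb <- diea_config(4, reduction = 2, gate_resize = "bilinear")
  y <- diea_forward(x, cfgb, w)
  expect_equal(dim(y), dim(x))
})

test_that("the full operator preserves shape across square sizes", {
  cfg <- diea_config(4, reduction = 2)
  w <- diea_init(cfg, seed = 10)
  set.seed(10)
  for (H in c(2, 4, 8, 16, 32)) {
    x <- rand_tensor(4, H, H)
    expect_equal(dim(diea_forward(x, cfg, w)), dim(x))
  }
  expect_error(diea_forward(rand_tensor(3, 4, 4), cfg, w), "channels")
})

test_that("pooling ablation variants coincide on constant inputs", {
  cfg_ap <- diea_config(5, reduction = 2, pool_mode = "AP_MP")
  w <- diea_init(cfg_ap, seed = 12)
  x <- array(2.5, c(5, 8, 8))
  y_apmp <- diea_forward(x, cfg_ap, w)
  for (pm in c("AP_AP", "MP_MP")) {
    cfg2 <- diea_config(5, reduction = 2, pool_mode = pm)
    expect_equal(diea_forward(x, cfg2, w), y_apmp)
  }
  # and differ on generic inputs
  set.seed(12)
  xr <- rand_tensor(5, 8, 8)
  cfg_aa <- diea_config(5, reduction = 2, pool_mode = "AP_AP")
  expect_gt(max(abs(diea_forward(xr, cfg_ap, w) -
                    diea_forward(xr, cfg_aa, w))), 1e-8)
})

test_that("the operator equals its step-by-step composition", {
  cfg <- diea_config(6, reduction = 2)
  w <- diea_init(cfg, seed = 14)
  set.seed(14)
  x <- rand_tensor(6, 8, 8)
  ap <- strip_avg_pool(x); mp <- strip_max_pool(x)
  cd <- concat_strips(c(ap, mp))
  h <- fuse_descriptors(cd, w, cfg)
  de <- split_and_expand(h, w, cfg)
  y_manual <- gate_and_apply(x, outer_embed(de), w, cfg)$y
  expect_lt(max(abs(diea_forward(x, cfg, w) - y_manual)), 1e-5)
})

test_that("coordinate attention factorises and matches the loop reference", {
  cfg <- diea_config(5, reduction = 2)
  w <- ca_init(cfg, seed = 21)
  set.seed(21)
  x <- rand_tensor(5, 6, 6)
  res <- ca_forward(x, cfg, w, with_gate = TRUE)
  # gate is rank one per channel (g[c,i,j] = g_h[c,i] g_w[c,j])
  expect_lt(max_rank1_residual(res$g), 1e-10)
  expect_lt(max(abs(res$y - loop_ca(x, cfg, w))), 1e-5)
  # constant input -> spatially constant gate
  gc <- ca_forward(array(1.7, c(5, 4, 4)), cfg, w, with_gate = TRUE)$g
  expect_lt(max(apply(gc, 1, function(m) diff(range(m)))), 1e-12)
})

test_that("the operator is differentiable with correct input gradients", {
  cfg <- diea_config(4, reduction = 2)
  w <- diea_init(cfg, seed = 17)
  set.seed(17)
  xb <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  fwd <- dieagrade:::diea_batch_forward(xb, cfg, w, training = TRUE,
                                        keep_cache = TRUE)
  dy <- cos(fwd$y)
  bk <- dieagrade:::diea_batch_backward(dy, fwd$cache, cfg, w)
  loss <- function(x) sum(sin(
    dieagrade:::diea_batch_forward(x, cfg, w, training = TRUE)$y))
  eps <- 1e-5
  idx <- sample(length(xb), 5)
  for (i in idx) {
    xp <- xb; xp[i] <- xp[i] + eps
    xm <- xb; xm[i] <- xm[i] - eps
    num <- (loss(xp) - loss(xm)) / (2 * eps)
    expect_lt(abs(num - bk$dx[i]) / (abs(num) + 1e-8), 1e-2)
    expect_true(is.finite(bk$dx[i]) && bk$dx[i] != 0)
  }
})
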