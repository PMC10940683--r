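# Batched forward/backward passes for the attention operators, used by the
# training framework. Batches are (C, H, W, N) arrays; BN statistics are
# taken over batch x positions in train mode, matching the per-sample
# operators (which this path reproduces exactly at N = 1 in eval mode).

strip_pool_batch <- function(xb, type) {
  d <- dim(xb); C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  if (type == "avg") {
    list(h = colSums(aperm(xb, c(3L, 1L, 2L, 4L))) / W,
         w = colSums(aperm(xb, c(2L, 1L, 3L, 4L))) / H,
         type = "avg")
  } else {
    mh <- matrix(aperm(xb, c(3L, 1L, 2L, 4L)), nrow = W)
    ah <- max.col(t(mh), ties.method = "first")
    mw <- matrix(aperm(xb, c(2L, 1L, 3L, 4L)), nrow = H)
    aw <- max.col(t(mw), ties.method = "first")
    list(h = array(mh[ah + W * (seq_along(ah) - 1L)], c(C, H, N)),
         w = array(mw[aw + H * (seq_along(aw) - 1L)], c(C, W, N)),
         arg_h = array(ah, c(C, H, N)), arg_w = array(aw, c(C, W, N)),
         type = "max")
  }
}

# accumulate strip-pool gradients (dh over rows, dw over cols) into dxb
strip_pool_backward <- function(dxb, pool, dh, dw) {
  d <- dim(dxb); C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  if (pool$type == "avg") {
    dxb <- dxb + aperm(array(dh / W, c(C, H, N, W)), c(1L, 2L, 4L, 3L))
    dxb <- dxb + aperm(array(dw / H, c(C, W, N, H)), c(1L, 4L, 2L, 3L))
  } else {
    lin <- slice.index(pool$arg_h, 1L) +
      C * ((slice.index(pool$arg_h, 2L) - 1L) +
             H * ((pool$arg_h - 1L) + W * (slice.index(pool$arg_h, 3L) - 1L)))
    dxb[lin] <- dxb[lin] + dh
    lin <- slice.index(pool$arg_w, 1L) +
      C * ((pool$arg_w - 1L) +
             H * ((slice.index(pool$arg_w, 2L) - 1L) +
                    W * (slice.index(pool$arg_w, 3L) - 1L)))
    dxb[lin] <- dxb[lin] + dw
  }
  dxb
}

expand_pq <- function(a, along) {
  # a is (C, S, N); replicate along the missing axis of (C, S, S, N):
  # along = "q" -> value at [c, p, q, n] = a[c, p, n]; along = "p" -> a[c, q, n]
  d <- dim(a); C <- d[1L]; S <- d[2L]; N <- d[3L]
  if (along == "q") aperm(array(a, c(C, S, N, S)), c(1L, 2L, 4L, 3L))
  else aperm(array(a, c(C, S, N, S)), c(1L, 4L, 2L, 3L))
}

diea_batch_forward <- function(xb, cfg, weights, training = FALSE,
                               keep_cache = FALSE) {
  d <- dim(xb); C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  if (H != W && cfg$gate_resize == "require_square")
    stop("non-square input requires gate_resize = 'bilinear'")
  S <- H + W; Cm <- cfg$mid_channels
  pa <- strip_pool_batch(xb, if (cfg$pool_mode == "MP_MP") "max" else "avg")
  pm <- strip_pool_batch(xb, if (cfg$pool_mode == "AP_AP") "avg" else "max")
  tarr <- array(0, c(C, 2L * S, N))
  tarr[, seq_len(H), ] <- pa$h
  tarr[, H + seq_len(W), ] <- pa$w
  tarr[, S + seq_len(H), ] <- pm$h
  tarr[, S + H + seq_len(W), ] <- pm$w
  tm <- matrix(tarr, C)
  u <- w1x1(weights$W1) %*% tm
  bn1c <- bn_forward(u, weights$bn1, training, cfg$bn_eps)
  h <- h_swish(bn1c$y)
  harr <- array(h, c(Cm, 2L * S, N))
  ham <- matrix(harr[, seq_len(S), , drop = FALSE], Cm)
  hmm <- matrix(harr[, S + seq_len(S), , drop = FALSE], Cm)
  va <- w1x1(weights$W2) %*% ham
  bn2c <- bn_forward(va, weights$bn2, training, cfg$bn_eps)
  vm <- w1x1(weights$W3) %*% hmm
  bn3c <- bn_forward(vm, weights$bn3, training, cfg$bn_eps)
  h_a <- array(bn2c$y, c(C, S, N))
  h_m <- array(bn3c$y, c(C, S, N))
  G0 <- expand_pq(h_a, "q") * expand_pq(h_m, "p")
  grp <- downsample_groups(cfg)
  z <- array(0, c(C, H, W, N))
  for (n in seq_len(N)) {
    zn <- conv2d(G0[, , , n, drop = TRUE], weights$Wd, weights$bd,
                 stride = 2L, pad = 1L, groups = grp)
    if (!identical(dim(zn)[2:3], c(H, W))) {
      zr <- array(0, c(C, H, W))
      for (c_ in seq_len(C)) zr[c_, , ] <- bilinear_resize(zn[c_, , ], H, W)
      zn <- zr
    }
    z[, , , n] <- zn
  }
  g <- sigmoid_(z)
  y <- xb * g
  if (training) {
    weights$bn1 <- bn_update_running(weights$bn1, bn1c, cfg$bn_momentum,
                                     ncol(u))
    weights$bn2 <- bn_update_running(weights$bn2, bn2c, cfg$bn_momentum,
                                     ncol(va))
    weights$bn3 <- bn_update_running(weights$bn3, bn3c, cfg$bn_momentum,
                                     ncol(vm))
  }
  cache <- if (keep_cache)
    list(xb = xb, pa = pa, pm = pm, tm = tm, bn1c = bn1c, ham = ham,
         hmm = hmm, bn2c = bn2c, bn3c = bn3c, h_a = h_a, h_m = h_m,
         G0 = G0, g = g, dims = d)
  else NULL
  list(y = y, g = g, cache = cache, weights = weights)
}

diea_batch_backward <- function(dy, cache, cfg, weights) {
  d <- cache$dims; C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  S <- H + W; Cm <- cfg$mid_channels
  if (!identical(dim(cache$G0)[2:3], c(S, S)) ||
      !identical(dim(cache$g)[2:3], c(H, W)))
    stop("backward requires the exact stride-2 geometry (square input)")
  g <- cache$g
  dg <- dy * cache$xb
  dx <- dy * g
  dz <- dg * g * (1 - g)
  grp <- downsample_groups(cfg)
  dWd <- array(0, dim(weights$Wd)); dbd <- rep(0, C)
  dG0 <- array(0, dim(cache$G0))
  for (n in seq_len(N)) {
    cb <- conv2d_backward(cache$G0[, , , n, drop = TRUE], weights$Wd,
                          dz[, , , n, drop = TRUE],
                          stride = 2L, pad = 1L, groups = grp)
    dG0[, , , n] <- cb$dx
    dWd <- dWd + cb$dw
    dbd <- dbd + cb$db
  }
  dh_a <- colSums(aperm(dG0 * expand_pq(cache$h_m, "p"), c(3L, 1L, 2L, 4L)))
  dh_m <- colSums(aperm(dG0 * expand_pq(cache$h_a, "q"), c(2L, 1L, 3L, 4L)))
  b2 <- bn_backward(cache$bn2c, weights$bn2, matrix(dh_a, C))
  b3 <- bn_backward(cache$bn3c, weights$bn3, matrix(dh_m, C))
  W2m <- w1x1(weights$W2); W3m <- w1x1(weights$W3)
  dW2 <- tcrossprod(b2$dx, cache$ham)
  dW3 <- tcrossprod(b3$dx, cache$hmm)
  dham <- crossprod(W2m, b2$dx)
  dhmm <- crossprod(W3m, b3$dx)
  dharr <- array(0, c(Cm, 2L * S, N))
  dharr[, seq_len(S), ] <- array(dham, c(Cm, S, N))
  dharr[, S + seq_len(S), ] <- array(dhmm, c(Cm, S, N))
  dhpre <- matrix(dharr, Cm) * h_swish_grad(cache$bn1c$y)
  b1 <- bn_backward(cache$bn1c, weights$bn1, dhpre)
  dW1 <- tcrossprod(b1$dx, cache$tm)
  dtm <- crossprod(w1x1(weights$W1), b1$dx)
  dtarr <- array(dtm, c(C, 2L * S, N))
  dx <- strip_pool_backward(dx, cache$pa,
                            dtarr[, seq_len(H), , drop = FALSE],
                            dtarr[, H + seq_len(W), , drop = FALSE])
  dx <- strip_pool_backward(dx, cache$pm,
                            dtarr[, S + seq_len(H), , drop = FALSE],
                            dtarr[, S + H + seq_len(W), , drop = FALSE])
  list(dx = dx,
       grads = list(W1 = array(dW1, dim(weights$W1)),
                    bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    W2 = array(dW2, dim(weights$W2)),
                    bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
                    W3 = array(dW3, dim(weights$W3)),
                    bn3 = list(gamma = b3$dgamma, beta = b3$dbeta),
                    Wd = dWd, bd = dbd))
}

ca_batch_forward <- function(xb, cfg, weights, training = FALSE,
                             keep_cache = FALSE) {
  d <- dim(xb); C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  S <- H + W; Cm <- cfg$mid_channels
  pa <- strip_pool_batch(xb, "avg")
  tarr <- array(0, c(C, S, N))
  tarr[, seq_len(H), ] <- pa$h
  tarr[, H + seq_len(W), ] <- pa$w
  tm <- matrix(tarr, C)
  u <- w1x1(weights$W1) %*% tm
  bn1c <- bn_forward(u, weights$bn1, training, cfg$bn_eps)
  h <- h_swish(bn1c$y)
  harr <- array(h, c(Cm, S, N))
  hh <- matrix(harr[, seq_len(H), , drop = FALSE], Cm)
  hw <- matrix(harr[, H + seq_len(W), , drop = FALSE], Cm)
  g_h <- sigmoid_(w1x1(weights$Wh) %*% hh)   # (C, H*N)
  g_w <- sigmoid_(w1x1(weights$Ww) %*% hw)   # (C, W*N)
  gh <- array(g_h, c(C, H, N)); gw <- array(g_w, c(C, W, N))
  g <- aperm(array(gh, c(C, H, N, W)), c(1L, 2L, 4L, 3L)) *
    aperm(array(gw, c(C, W, N, H)), c(1L, 4L, 2L, 3L))
  y <- xb * g
  if (training)
    weights$bn1 <- bn_update_running(weights$bn1, bn1c, cfg$bn_momentum,
                                     ncol(u))
  cache <- if (keep_cache)
    list(xb = xb, pa = pa, tm = tm, bn1c = bn1c, hh = hh, hw = hw,
         gh = gh, gw = gw, g = g, dims = d)
  else NULL
  list(y = y, g = g, cache = cache, weights = weights)
}

ca_batch_backward <- function(dy, cache, cfg, weights) {
  d <- cache$dims; C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  Cm <- cfg$mid_channels
  dg <- dy * cache$xb
  dx <- dy * cache$g
  gwf <- aperm(array(cache$gw, c(C, W, N, H)), c(1L, 4L, 2L, 3L))
  ghf <- aperm(array(cache$gh, c(C, H, N, W)), c(1L, 2L, 4L, 3L))
  dgh <- colSums(aperm(dg * gwf, c(3L, 1L, 2L, 4L)))          # (C, H, N)
  dgw <- colSums(aperm(dg * ghf, c(2L, 1L, 3L, 4L)))          # (C, W, N)
  ghm <- matrix(cache$gh, C); gwm <- matrix(cache$gw, C)
  duh <- matrix(dgh, C) * ghm * (1 - ghm)
  duw <- matrix(dgw, C) * gwm * (1 - gwm)
  dWh <- tcrossprod(duh, cache$hh)
  dWw <- tcrossprod(duw, cache$hw)
  dhh <- crossprod(w1x1(weights$Wh), duh)
  dhw <- crossprod(w1x1(weights$Ww), duw)
  dharr <- array(0, c(Cm, H + W, N))
  dharr[, seq_len(H), ] <- array(dhh, c(Cm, H, N))
  dharr[, H + seq_len(W), ] <- array(dhw, c(Cm, W, N))
  dhpre <- matrix(dharr, Cm) * h_swish_grad(cache$bn1c$y)
  b1 <- bn_backward(cache$bn1c, weights$bn1, dhpre)
  dW1 <- tcrossprod(b1$dx, cache$tm)
  dtarr <- array(crossprod(w1x1(weights$W1), b1$dx), c(C, H + W, N))
  dx <- strip_pool_backward(dx, cache$pa,
                            dtarr[, seq_len(H), , drop = FALSE],
                            dtarr[, H + seq_len(W), , drop = FALSE])
  list(dx = dx,
       grads = list(W1 = array(dW1, dim(weights$W1)),
                    bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    Wh = array(dWh, dim(weights$Wh)),
                    Ww = array(dWw, dim(weights$Ww))))
}
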