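# Independent oracles used across the suite: explicit double/triple-loop
# implementations of the pooling, outer-product and coordinate-attention
# equations, an indicator-matrix Matthews correlation, and a
# finite-difference gradient probe. These deliberately avoid the vectorised
# code paths they check.

rand_tensor <- function(C, H, W) array(stats::rnorm(C * H * W), c(C, H, W))

loop_strip_avg <- function(x) {
  d <- dim(x)
  a_h <- matrix(0, d[1], d[2]); a_w <- matrix(0, d[1], d[3])
  for (c in seq_len(d[1])) {
    for (h in seq_len(d[2])) {
      s <- 0
      for (i in seq_len(d[3])) s <- s + x[c, h, i]
      a_h[c, h] <- s / d[3]
    }
    for (w in seq_len(d[3])) {
      s <- 0
      for (j in seq_len(d[2])) s <- s + x[c, j, w]
      a_w[c, w] <- s / d[2]
    }
  }
  list(a_h = a_h, a_w = a_w)
}

loop_strip_max <- function(x) {
  d <- dim(x)
  m_h <- matrix(-Inf, d[1], d[2]); m_w <- matrix(-Inf, d[1], d[3])
  for (c in seq_len(d[1])) {
    for (h in seq_len(d[2])) for (i in seq_len(d[3]))
      m_h[c, h] <- max(m_h[c, h], x[c, h, i])
    for (w in seq_len(d[3])) for (j in seq_len(d[2]))
      m_w[c, w] <- max(m_w[c, w], x[c, j, w])
  }
  list(m_h = m_h, m_w = m_w)
}

loop_outer <- function(h_a, h_m) {
  C <- dim(h_a)[1]; S <- dim(h_a)[2]
  out <- array(0, c(C, S, S))
  for (c in seq_len(C)) for (p in seq_len(S)) for (q in seq_len(S))
    out[c, p, q] <- h_a[c, p, 1] * h_m[c, 1, q]
  out
}

# coordinate attention computed per-position from its defining equations,
# independent of the package's vectorised path
loop_ca <- function(x, cfg, w) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  pool <- loop_strip_avg(x)
  t <- cbind(pool$a_h, pool$a_w)
  W1 <- matrix(w$W1, nrow = dim(w$W1)[1])
  u <- matrix(0, nrow(W1), H + W)
  for (l in seq_len(H + W)) u[, l] <- W1 %*% t[, l]
  bn <- (u - w$bn1$running_mean) / sqrt(w$bn1$running_var + cfg$bn_eps) *
    w$bn1$gamma + w$bn1$beta
  hsw <- bn * pmin(pmax(bn + 3, 0), 6) / 6
  Wh <- matrix(w$Wh, nrow = dim(w$Wh)[1])
  Ww <- matrix(w$Ww, nrow = dim(w$Ww)[1])
  gh <- 1 / (1 + exp(-(Wh %*% hsw[, seq_len(H), drop = FALSE])))
  gw <- 1 / (1 + exp(-(Ww %*% hsw[, H + seq_len(W), drop = FALSE])))
  y <- x
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(W))
    y[c, i, j] <- x[c, i, j] * gh[c, i] * gw[c, j]
  y
}

# multiclass Matthews correlation via Pearson correlation of flattened
# one-hot indicator matrices (covariance form), independent of the
# confusion-matrix closed form
mcc_indicator <- function(truth, pred, k) {
  X <- matrix(0, length(truth), k); Y <- matrix(0, length(pred), k)
  X[cbind(seq_along(truth), truth)] <- 1
  Y[cbind(seq_along(pred), pred)] <- 1
  cov_xy <- sum(diag(stats::cov(X, Y)))
  cov_xx <- sum(diag(stats::cov(X, X)))
  cov_yy <- sum(diag(stats::cov(Y, Y)))
  if (cov_xx == 0 || cov_yy == 0) return(0)
  cov_xy / sqrt(cov_xx * cov_yy)
}

# labels drawn so every class appears; returns truth/pred/cm triple
rand_labels_cm <- function(n, k) {
  truth <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  pred <- sample.int(k, n, replace = TRUE)
  list(truth = truth, pred = pred, cm = confusion_matrix(truth, pred, k))
}

max_rank1_residual <- function(h_am) {
  max(vapply(seq_len(dim(h_am)[1]), function(c) {
    sv <- svd(h_am[c, , ])$d
    if (sv[1] < 1e-12) 0 else sv[2] / sv[1]
  }, numeric(1)))
}
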