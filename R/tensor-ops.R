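# Low-level numeric kernels shared by the attention operator, the backbone
# interpreter and the small training framework. Feature maps are plain R
# arrays indexed (channel, row, col); batches append a trailing sample axis.

#' Hard-swish activation
#'
#' Elementwise `x * clamp(x + 3, 0, 6) / 6`, the piecewise-polynomial
#' approximation of swish used throughout the attention bottleneck.
#'
#' @param x numeric vector or array.
#' @return object of the same shape as `x`.
#' @examples
#' h_swish(c(-4, -3, 0, 1, 3, 5))
#' @export
h_swish <- function(x) {
  x * pmin(pmax(x + 3, 0), 6) / 6
}

# derivative of h_swish, used by the backward pass
h_swish_grad <- function(x) {
  ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

conv_out_len <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

pad_chw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad))
  xp[, (pad + 1L):(pad + d[2L]), (pad + 1L):(pad + d[3L])] <- x
  xp
}

# im2col linear indices into a (cin, Hp, Wp) padded array.
# Rows enumerate (c, kh, kw); columns enumerate output positions (ho, wo).
im2col_index <- function(cin, Hp, Wp, kh, kw, stride, Ho, Wo) {
  cc <- rep.int(seq_len(cin), kh * kw)
  ii <- rep(rep(seq_len(kh), each = cin), kw)
  jj <- rep(seq_len(kw), each = cin * kh)
  base <- cc + cin * ((ii - 1L) + Hp * (jj - 1L))
  ho <- rep.int(seq_len(Ho), Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  offs <- cin * ((ho - 1L) * stride + Hp * ((wo - 1L) * stride))
  outer(base, offs, `+`)
}

#' 2-D convolution on a single (C, H, W) feature map
#'
#' Direct im2col + BLAS implementation supporting stride, zero padding and
#' channel groups (depthwise convolution takes a fast shift-accumulate path).
#' Weights are stored torch-style as a `(cout, cin/groups, kh, kw)` array.
#'
#' @param x numeric array `(C, H, W)`.
#' @param w numeric array `(cout, cin/groups, kh, kw)`.
#' @param bias optional numeric vector of length `cout`.
#' @param stride,pad integer stride and symmetric zero padding.
#' @param groups number of channel groups.
#' @return numeric array `(cout, Ho, Wo)`.
#' @keywords internal
conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]
  dw <- dim(w); cout <- dw[1L]; cing <- dw[2L]; kh <- dw[3L]; kw <- dw[4L]
  stopifnot(C == cing * groups, cout %% groups == 0L)
  Ho <- conv_out_len(H, kh, stride, pad); Wo <- conv_out_len(W, kw, stride, pad)
  if (Ho < 1L || Wo < 1L) stop("convolution output collapsed to zero size")
  xp <- pad_chw(x, pad)
  Hp <- dim(xp)[2L]; Wp <- dim(xp)[3L]
  if (groups == C && cing == 1L && cout == C) {
    # depthwise fast path: one fused multiply-add per kernel tap
    y <- array(0, c(C, Ho, Wo))
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      rows <- seq.int(i, by = stride, length.out = Ho)
      cols <- seq.int(j, by = stride, length.out = Wo)
      y <- y + w[, 1L, i, j] * xp[, rows, cols, drop = FALSE]
    }
  } else {
    y <- array(0, c(cout, Ho, Wo))
    coutg <- cout %/% groups
    for (g in seq_len(groups)) {
      chg <- ((g - 1L) * cing + 1L):(g * cing)
      xg <- xp[chg, , , drop = FALSE]
      idx <- im2col_index(cing, Hp, Wp, kh, kw, stride, Ho, Wo)
      colsm <- matrix(xg[idx], nrow = nrow(idx))
      wg <- matrix(aperm(w[((g - 1L) * coutg + 1L):(g * coutg), , , ,
                           drop = FALSE], c(2L, 3L, 4L, 1L)),
                   ncol = coutg)
      y[((g - 1L) * coutg + 1L):(g * coutg), , ] <-
        array(t(crossprod(colsm, wg)), c(coutg, Ho, Wo))
    }
  }
  if (!is.null(bias)) y <- y + bias
  y
}

# Backward of conv2d (groups == 1 or depthwise) w.r.t. input, weight, bias.
# Returns list(dx, dw, db). `x` is the forward input, `dy` the upstream grad.
conv2d_backward <- function(x, w, dy, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]
  dw_ <- dim(w); cout <- dw_[1L]; cing <- dw_[2L]; kh <- dw_[3L]; kw <- dw_[4L]
  Ho <- dim(dy)[2L]; Wo <- dim(dy)[3L]
  xp <- pad_chw(x, pad)
  Hp <- dim(xp)[2L]; Wp <- dim(xp)[3L]
  dxp <- array(0, dim(xp))
  dw <- array(0, dim(w))
  if (groups == C && cing == 1L && cout == C) {
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      rows <- seq.int(i, by = stride, length.out = Ho)
      cols <- seq.int(j, by = stride, length.out = Wo)
      xs <- xp[, rows, cols, drop = FALSE]
      dw[, 1L, i, j] <- rowSums(matrix(xs * dy, nrow = C))
      dxp[, rows, cols] <- dxp[, rows, cols] + w[, 1L, i, j] * dy
    }
  } else if (groups == 1L) {
    idx <- im2col_index(C, Hp, Wp, kh, kw, stride, Ho, Wo)
    colsm <- matrix(xp[idx], nrow = nrow(idx))
    dym <- matrix(dy, nrow = cout)
    dw[] <- array(tcrossprod(dym, colsm), c(cout, C, kh, kw))
    wm <- matrix(aperm(w, c(2L, 3L, 4L, 1L)), ncol = cout)
    dcols <- wm %*% dym
    for (r in seq_len(nrow(idx))) {
      dxp[idx[r, ]] <- dxp[idx[r, ]] + dcols[r, ]
    }
  } else {
    stop("conv2d_backward supports groups == 1 or depthwise only")
  }
  dx <- if (pad > 0L)
    dxp[, (pad + 1L):(pad + H), (pad + 1L):(pad + W), drop = FALSE]
  else dxp
  list(dx = dx, dw = dw, db = rowSums(matrix(dy, nrow = cout)))
}

# 1-D batch normalisation on a (C, M) matrix of per-channel observations.
# mode "train" uses column statistics of the batch, "eval" the running stats.
bn_forward <- function(xm, bn, training = FALSE, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv
  list(y = bn$gamma * xhat + bn$beta, xhat = xhat, inv = inv, mu = mu, var = v)
}

bn_backward <- function(cache, bn, dy) {
  M <- ncol(dy)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dx <- (bn$gamma * cache$inv) *
    (dy - dbeta / M - cache$xhat * (dgamma / M))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_update_running <- function(bn, cache, momentum = 0.1, M = NULL) {
  vu <- cache$var
  if (!is.null(M) && M > 1L) vu <- vu * M / (M - 1L)  # unbiased for running
  bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * cache$mu
  bn$running_var <- (1 - momentum) * bn$running_var + momentum * vu
  bn
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       running_mean = rep(0, c), running_var = rep(1, c))
}

# 2x2/s2-style max pooling on (C, H, W); returns pooled map and argmax indices
maxpool2d <- function(x, k = 2L, stride = 2L) {
  d <- dim(x); C <- d[1L]
  Ho <- conv_out_len(d[2L], k, stride, 0L); Wo <- conv_out_len(d[3L], k, stride, 0L)
  y <- array(-Inf, c(C, Ho, Wo))
  arg <- array(0L, c(C, Ho, Wo))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    rows <- seq.int(i, by = stride, length.out = Ho)
    cols <- seq.int(j, by = stride, length.out = Wo)
    cand <- x[, rows, cols, drop = FALSE]
    lin <- outer(seq_len(C),
                 C * outer(rows - 1L, (cols - 1L) * d[2L], `+`), `+`)
    dim(lin) <- c(C, Ho, Wo)
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- lin[upd]
  }
  list(y = y, argmax = arg)
}

maxpool2d_backward <- function(xdim, pool, dy) {
  dx <- array(0, xdim)
  dx[as.vector(pool$argmax)] <- dx[as.vector(pool$argmax)] + as.vector(dy)
  # ties across windows are impossible (disjoint windows when k == stride)
  dx
}

# bilinear resize of a (H, W) matrix (align_corners = FALSE convention)
bilinear_resize <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  if (H == out_h && W == out_w) return(m)
  ry <- (seq_len(out_h) - 0.5) * H / out_h - 0.5
  rx <- (seq_len(out_w) - 0.5) * W / out_w - 0.5
  y0 <- pmin(pmax(floor(ry), 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(pmax(floor(rx), 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * (1 - rep(wx, each = out_h)) + b * rep(wx, each = out_h)
  bot <- c_ * (1 - rep(wx, each = out_h)) + d * rep(wx, each = out_h)
  top * (1 - wy) + bot * wy
}

# Kaiming-uniform initialisation for a conv/linear weight array
kaiming_uniform <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

assert_feature_map <- function(x, what = "x") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("%s must be a (C, H, W) array", what))
  if (any(dim(x) < 1L)) stop(sprintf("%s has an empty dimension", what))
  if (!all(is.finite(x))) stop(sprintf("%s contains non-finite entries", what))
  invisible(TRUE)
}
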