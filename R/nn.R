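# Minimal training framework for desk-scale experiments: sequential models
# over (C, H, W, N) batches with hand-derived backward passes, softmax
# cross-entropy and decoupled-weight-decay Adam. Big enough to train the
# tiny grading CNN with an attention block; not a general autograd.

layer_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                       name = "conv") {
  list(type = "conv", name = name, cin = cin, cout = cout, k = k,
       stride = stride, pad = pad,
       w = kaiming_uniform(c(cout, cin, k, k), cin * k * k),
       b = rep(0, cout))
}
layer_relu <- function(name = "relu") list(type = "relu", name = name)
layer_maxpool <- function(k = 2L, name = "pool")
  list(type = "maxpool", name = name, k = k)
layer_gap <- function(name = "gap") list(type = "gap", name = name)
layer_linear <- function(cin, cout, name = "fc") {
  list(type = "linear", name = name, cin = cin, cout = cout,
       w = kaiming_uniform(c(cout, cin), cin), b = rep(0, cout))
}
layer_attention <- function(kind, channels, name = "attn") {
  cfg <- diea_config(channels)
  list(type = kind, name = name, cfg = cfg,
       weights = if (kind == "diea") diea_init(cfg) else ca_init(cfg))
}

#' Build the tiny grading CNN
#'
#' Two 3x3 convolution + ReLU + 2x2 max-pool stages, an optional attention
#' block on the final feature map, global average pooling and a linear
#' head. Used for the desk-scale pipeline experiment (downsampled inputs),
#' not a substitute for the full backbones of [build_model()].
#'
#' @param num_classes number of output classes.
#' @param attention `"diea"`, `"ca"` or `"none"`.
#' @param channels widths of the two conv stages.
#' @param input_size spatial input size (must be divisible by 4).
#' @param seed weight-initialisation seed.
#' @return object of class `tiny_cnn`.
#' @export
tiny_cnn <- function(num_classes = 3L, attention = c("diea", "ca", "none"),
                     channels = c(8L, 16L), input_size = 32L, seed = 1L) {
  attention <- match.arg(attention)
  stopifnot(input_size %% 4L == 0L)
  set.seed(seed)
  layers <- list(
    layer_conv(3L, channels[1L], name = "conv1"),
    layer_relu("relu1"),
    layer_maxpool(name = "pool1"),
    layer_conv(channels[1L], channels[2L], name = "conv2"),
    layer_relu("relu2"),
    layer_maxpool(name = "pool2"))
  if (attention != "none")
    layers <- c(layers, list(layer_attention(attention, channels[2L])))
  layers <- c(layers, list(layer_gap(),
                           layer_linear(channels[2L], num_classes)))
  structure(list(layers = layers, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size), attention = attention),
            class = "tiny_cnn")
}

layer_forward <- function(layer, x, training = FALSE, keep = FALSE) {
  switch(layer$type,
    conv = {
      N <- dim(x)[4L]
      Ho <- conv_out_len(dim(x)[2L], layer$k, layer$stride, layer$pad)
      Wo <- conv_out_len(dim(x)[3L], layer$k, layer$stride, layer$pad)
      y <- array(0, c(layer$cout, Ho, Wo, N))
      for (n in seq_len(N))
        y[, , , n] <- conv2d(x[, , , n, drop = TRUE], layer$w, layer$b,
                             layer$stride, layer$pad)
      list(y = y, cache = if (keep) list(x = x), layer = layer)
    },
    relu = list(y = pmax(x, 0), cache = if (keep) list(mask = x > 0),
                layer = layer),
    maxpool = {
      N <- dim(x)[4L]
      pools <- vector("list", N)
      y <- NULL
      for (n in seq_len(N)) {
        p <- maxpool2d(x[, , , n, drop = TRUE], layer$k, layer$k)
        if (is.null(y)) y <- array(0, c(dim(p$y), N))
        y[, , , n] <- p$y
        pools[[n]] <- p
      }
      list(y = y, cache = if (keep) list(pools = pools, xdim = dim(x)),
           layer = layer)
    },
    gap = {
      d <- dim(x)
      arr <- array(x, c(d[1L], d[2L] * d[3L], d[4L]))
      list(y = apply(arr, c(1L, 3L), mean),
           cache = if (keep) list(xdim = d), layer = layer)
    },
    linear = list(y = layer$w %*% x + layer$b,
                  cache = if (keep) list(x = x), layer = layer),
    diea = {
      r <- diea_batch_forward(x, layer$cfg, layer$weights, training,
                              keep_cache = keep)
      layer$weights <- r$weights
      list(y = r$y, cache = r$cache, layer = layer)
    },
    ca = {
      r <- ca_batch_forward(x, layer$cfg, layer$weights, training,
                            keep_cache = keep)
      layer$weights <- r$weights
      list(y = r$y, cache = r$cache, layer = layer)
    },
    stop("unknown layer type ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      N <- dim(dy)[4L]
      dx <- array(0, dim(cache$x))
      dw <- array(0, dim(layer$w)); db <- rep(0, length(layer$b))
      for (n in seq_len(N)) {
        cb <- conv2d_backward(cache$x[, , , n, drop = TRUE], layer$w,
                              dy[, , , n, drop = TRUE],
                              layer$stride, layer$pad)
        dx[, , , n] <- cb$dx; dw <- dw + cb$dw; db <- db + cb$db
      }
      list(dx = dx, grads = list(w = dw, b = db))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    maxpool = {
      N <- dim(dy)[4L]
      dx <- array(0, cache$xdim)
      for (n in seq_len(N))
        dx[, , , n] <- maxpool2d_backward(cache$xdim[1:3], cache$pools[[n]],
                                          dy[, , , n, drop = TRUE])
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$xdim
      list(dx = aperm(array(dy / (d[2L] * d[3L]),
                            c(d[1L], d[4L], d[2L], d[3L])),
                      c(1L, 3L, 4L, 2L)),
           grads = NULL)
    },
    linear = list(dx = crossprod(layer$w, dy),
                  grads = list(w = tcrossprod(dy, cache$x),
                               b = rowSums(dy))),
    diea = {
      r <- diea_batch_backward(dy, cache, layer$cfg, layer$weights)
      list(dx = r$dx, grads = r$grads)
    },
    ca = {
      r <- ca_batch_backward(dy, cache, layer$cfg, layer$weights)
      list(dx = r$dx, grads = r$grads)
    },
    stop("unknown layer type ", layer$type)
  )
}

#' Forward pass of a tiny CNN on a batch
#'
#' @param model a [tiny_cnn()].
#' @param xb numeric `(3, S, S, N)` batch.
#' @param training train-mode BN (batch statistics + running updates).
#' @param keep keep caches for a backward pass.
#' @return list with `logits` (K x N), `caches`, and the (possibly
#'   BN-updated) `model`.
#' @export
nn_forward <- function(model, xb, training = FALSE, keep = FALSE) {
  caches <- vector("list", length(model$layers))
  x <- xb
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], x, training, keep)
    x <- r$y
    caches[[i]] <- r$cache
    model$layers[[i]] <- r$layer
  }
  list(logits = x, caches = caches, model = model)
}

# backward from dlogits; optionally stop after reaching layer `until`
# (returns the gradient w.r.t. that layer's output)
nn_backward <- function(model, caches, dlogits, until = 0L) {
  grads <- vector("list", length(model$layers))
  dy <- dlogits
  for (i in rev(seq_along(model$layers))) {
    if (i == until) return(list(grads = grads, d_out = dy))
    r <- layer_backward(model$layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)  # keep NULL slots (parameter-free layers)
  }
  list(grads = grads, dx = dy)
}

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2L, apply(z, 2L, max)))
  sweep(z, 2L, colSums(z), "/")
}

# cross-entropy loss and gradient; labels are 1-based class indices
softmax_ce <- function(logits, labels) {
  p <- softmax_cols(logits)
  N <- ncol(logits)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[cbind(labels, seq_len(N))], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  list(loss = loss, dlogits = dp / N, probs = p)
}

# ---- decoupled-weight-decay Adam over nested grad/param trees ----

adamw_init <- function() list(t = 0L, m = list(), v = list())

# names of parameter leaves that receive weight decay (weights, not
# biases/BN affine terms)
decayed_leaf <- function(name)
  name %in% c("w", "W1", "W2", "W3", "Wd", "Wh", "Ww")

adamw_tree <- function(params, grads, m, v, lr, wd, beta1, beta2, eps,
                       bc1, bc2, decay_parent = FALSE) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.list(g)) {
      if (length(m[[nm]] %||% list()) == 0L) { m[[nm]] <- list(); v[[nm]] <- list() }
      r <- adamw_tree(params[[nm]], g, m[[nm]], v[[nm]], lr, wd,
                      beta1, beta2, eps, bc1, bc2)
      params[[nm]] <- r$params; m[[nm]] <- r$m; v[[nm]] <- r$v
    } else {
      if (is.null(m[[nm]])) { m[[nm]] <- g * 0; v[[nm]] <- g * 0 }
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
      step <- lr * (m[[nm]] / bc1) / (sqrt(v[[nm]] / bc2) + eps)
      if (decayed_leaf(nm)) step <- step + lr * wd * params[[nm]]
      params[[nm]] <- params[[nm]] - step
    }
  }
  list(params = params, m = m, v = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layer_param_names <- function(layer)
  switch(layer$type,
    conv = , linear = c("w", "b"),
    diea = , ca = "weights",
    NULL)

# one optimiser step over all layers; state carries per-layer moments
adamw_step <- function(model, grads, state, lr, wd = 1e-2,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  nl <- length(model$layers)
  if (length(state$m) < nl) length(state$m) <- length(state$v) <- nl
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    lay <- model$layers[[i]]
    if (lay$type %in% c("diea", "ca")) {
      r <- adamw_tree(lay$weights, g, state$m[[i]] %||% list(),
                      state$v[[i]] %||% list(), lr, wd, beta1, beta2, eps,
                      bc1, bc2)
      # BN running stats are not grad leaves and pass through untouched
      lay$weights <- r$params
      state$m[[i]] <- r$m; state$v[[i]] <- r$v
    } else {
      r <- adamw_tree(lay[c("w", "b")], g, state$m[[i]] %||% list(),
                      state$v[[i]] %||% list(), lr, wd, beta1, beta2, eps,
                      bc1, bc2)
      lay$w <- r$params$w; lay$b <- r$params$b
      state$m[[i]] <- r$m; state$v[[i]] <- r$v
    }
    model$layers[[i]] <- lay
  }
  list(model = model, state = state)
}

#' @export
count_params.tiny_cnn <- function(model) {
  tot <- 0
  for (lay in model$layers) {
    if (lay$type %in% c("conv", "linear"))
      tot <- tot + length(lay$w) + length(lay$b)
    if (lay$type %in% c("diea", "ca"))
      tot <- tot + sum(vapply(lay$weights, function(p)
        if (is.list(p)) length(p$gamma) + length(p$beta) else length(p),
        numeric(1)))
  }
  tot / 1e6
}
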