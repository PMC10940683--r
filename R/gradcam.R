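# Gradient-weighted class activation mapping on the tiny CNN: the gradient
# of a class logit at a convolutional (or attention) feature layer weights
# the layer's channels; the rectified weighted sum, upsampled and min-max
# normalised, localises the image evidence for that class.

#' Min-max normalise a heatmap to [0, 1]
#'
#' An all-constant map becomes all-zero, so normalisation is idempotent.
#'
#' @param h numeric matrix.
#' @return matrix with min 0 and max 1 (or all zeros).
#' @export
normalize_heatmap <- function(h) {
  rng <- range(h)
  if (rng[2] - rng[1] <= 0) return(h * 0)
  (h - rng[1]) / (rng[2] - rng[1])
}

heat_color <- function(v) {
  # simple blue -> red colormap on [0,1]
  r <- pmin(pmax(1.5 * v - 0.25, 0), 1)
  g <- pmin(pmax(1 - abs(2 * v - 1), 0), 1) * 0.8
  b <- pmin(pmax(1.25 - 1.5 * v, 0), 1)
  list(r = r, g = g, b = b)
}

#' Grad-CAM heatmap for one image and class
#'
#' @param model a trained [tiny_cnn()].
#' @param image `(H, W, 3)` RGB array (0..255) or a `(3, S, S)` input
#'   tensor already on the model scale.
#' @param target_class class index (1-based); defaults to the predicted
#'   class.
#' @param target_layer name of the feature layer whose activations are
#'   weighted (default: the last convolutional or attention layer).
#' @return object of class `heatmap`: list with `values` (input-resolution
#'   matrix in \[0, 1\]), `overlay` (RGB composite, 0..255), `target_class`
#'   and `layer`.
#' @export
grad_cam <- function(model, image, target_class = NULL, target_layer = NULL) {
  feat_layers <- vapply(model$layers, function(l)
    if (l$type %in% c("conv", "diea", "ca")) l$name else NA_character_,
    character(1))
  valid <- feat_layers[!is.na(feat_layers)]
  if (is.null(target_layer)) target_layer <- valid[length(valid)]
  li <- which(feat_layers == target_layer)
  if (length(li) != 1L)
    stop("target_layer '", target_layer, "' not found; valid layers: ",
         paste(valid, collapse = ", "))
  s <- model$input_size
  if (length(dim(image)) == 3L && dim(image)[3L] == 3L &&
      dim(image)[1L] != 3L) {
    # raw RGB patch: downsample and standardise like the training loader
    f <- nrow(image) %/% s
    x <- array(0, c(3L, s, s))
    for (ch in 1:3) x[ch, , ] <- block_mean(image[, , ch], f) / 255 - 0.5
    if (!is.null(model$norm_stats))
      for (ch in 1:3) x[ch, , ] <-
        (x[ch, , ] - model$norm_stats[ch, 1L]) / model$norm_stats[ch, 2L]
    img_disp <- image
  } else {
    x <- image
    img_disp <- NULL
  }
  xb <- array(x, c(dim(x), 1L))
  fwd <- nn_forward(model, xb, training = FALSE, keep = TRUE)
  k <- nrow(fwd$logits)
  if (is.null(target_class)) target_class <- which.max(fwd$logits[, 1L])
  dlog <- matrix(0, k, 1L)
  dlog[target_class, 1L] <- 1
  bk <- nn_backward(fwd$model, fwd$caches, dlog, until = li)
  # activation at the target layer's output: re-run forward up to li
  act <- xb
  for (i in seq_len(li)) act <- layer_forward(model$layers[[i]], act)$y
  act <- act[, , , 1L, drop = TRUE]
  grad <- bk$d_out[, , , 1L, drop = TRUE]
  wts <- rowMeans(matrix(grad, dim(grad)[1L]))
  cam <- apply(act * wts, c(2L, 3L), sum)
  cam <- pmax(cam, 0)
  cam_up <- bilinear_resize(cam, s, s)
  vals <- normalize_heatmap(cam_up)
  if (!is.null(img_disp)) {
    vals_full <- normalize_heatmap(
      bilinear_resize(cam, nrow(img_disp), ncol(img_disp)))
    hc <- heat_color(vals_full)
    overlay <- img_disp * 0.5
    overlay[, , 1L] <- overlay[, , 1L] + 127.5 * hc$r
    overlay[, , 2L] <- overlay[, , 2L] + 127.5 * hc$g
    overlay[, , 3L] <- overlay[, , 3L] + 127.5 * hc$b
    vals <- vals_full
  } else {
    hc <- heat_color(vals)
    overlay <- array(0, c(nrow(vals), ncol(vals), 3L))
    overlay[, , 1L] <- 255 * hc$r
    overlay[, , 2L] <- 255 * hc$g
    overlay[, , 3L] <- 255 * hc$b
  }
  structure(list(values = vals, overlay = round(overlay),
                 target_class = target_class, layer = target_layer),
            class = "heatmap")
}

#' Save a heatmap as grayscale PNG plus JPEG overlay
#'
#' @param hm a `heatmap` from [grad_cam()].
#' @param path_gray grayscale PNG path.
#' @param path_overlay overlay JPEG path (optional).
#' @export
save_heatmap <- function(hm, path_gray, path_overlay = NULL) {
  png::writePNG(hm$values, path_gray)
  if (!is.null(path_overlay))
    jpeg::writeJPEG(pmin(pmax(hm$overlay, 0), 255) / 255, path_overlay,
                    quality = 0.92)
  invisible(path_gray)
}
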