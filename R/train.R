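# Training recipe and evaluation metrics. The published recipe (AdamW,
# lr 1e-4, weight decay 1e-2, batch 16, 256 x 256 inputs, 200 epochs with a
# one-epoch linear warmup and cosine annealing to zero, cross-entropy) is
# the default configuration; the desk-scale smoke configuration trains the
# tiny CNN on downsampled inputs for a handful of epochs.

#' Training configuration
#'
#' @param batch_size minibatch size.
#' @param input_size model input side length; patches are block-averaged
#'   down to this size when smaller than the stored patch.
#' @param lr peak learning rate.
#' @param weight_decay decoupled weight decay of AdamW.
#' @param epochs total epochs (epoch 1 carries the linear warmup).
#' @param warmup_epochs warmup length in epochs.
#' @param seed seed controlling initialisation and shuffling.
#' @export
train_config <- function(batch_size = 16L, input_size = 256L, lr = 1e-4,
                         weight_decay = 1e-2, epochs = 200L,
                         warmup_epochs = 1L, seed = 1L) {
  if (lr <= 0) stop("lr must be positive")
  if (epochs < warmup_epochs) stop("epochs must be at least warmup_epochs")
  structure(list(batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), lr = lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale smoke-training configuration
#'
#' Tiny-CNN settings for the end-to-end pipeline experiment: 32 x 32
#' block-averaged inputs, 10 epochs, lr 1e-2.
#' @export
smoke_config <- function()
  train_config(batch_size = 16L, input_size = 32L, lr = 1e-2, epochs = 10L)

#' Learning rate at an epoch
#'
#' Epoch 0 is the linear warmup (ramping to `lr` across the epoch; the
#' `frac` argument gives the within-epoch position). Epochs `1..epochs`
#' follow cosine annealing `lr/2 (1 + cos(pi (e-1)/(epochs-1)))`, reaching
#' exactly 0 at the final epoch.
#'
#' @param e epoch index in `0..cfg$epochs`.
#' @param cfg a [train_config()].
#' @param frac within-epoch fraction for the warmup epoch.
#' @return learning rate.
#' @export
lr_at_epoch <- function(e, cfg, frac = 1) {
  if (e < 0 || e > cfg$epochs) stop("epoch ", e, " outside [0, ", cfg$epochs, "]")
  if (e == 0) return(cfg$lr * frac)
  if (cfg$epochs == 1L) return(0)
  cfg$lr * 0.5 * (1 + cos(pi * (e - 1) / (cfg$epochs - 1)))
}

#' Confusion matrix from labels
#'
#' @param truth,pred integer class indices (1-based) or factors on the same
#'   levels.
#' @param k number of classes.
#' @return `k x k` integer matrix, rows = true class, cols = predicted.
#' @export
confusion_matrix <- function(truth, pred, k = max(truth, pred)) {
  cm <- matrix(0L, k, k)
  for (i in seq_along(truth))
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

#' Compute the nine-metric performance report from a confusion matrix
#'
#' Accuracy, per-class precision/recall/F1 with macro (unweighted mean) and
#' weighted (support-weighted) averages, the multiclass Matthews
#' correlation (K-category R_k from the confusion matrix), Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)`, and -- when per-class scores are supplied --
#' macro and weighted one-vs-rest AUC.
#'
#' @param cm confusion matrix (rows = truth, cols = prediction).
#' @param scores optional N x K matrix of class probabilities.
#' @param truth optional length-N integer truth labels matching `scores`.
#' @return object of class `metric_report` (a named list).
#' @export
compute_metrics <- function(cm, scores = NULL, truth = NULL) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  if (n == 0L || nrow(cm) != ncol(cm)) stop("empty or non-square confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  rs <- rowSums(cm)   # support per true class
  cs <- colSums(cm)   # predictions per class
  if (any(rs == 0L))
    warning("class(es) with zero support: per-class metrics set to 0")
  prec <- ifelse(cs > 0, tp / cs, 0)
  rec <- ifelse(rs > 0, tp / rs, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- rs / n
  acc <- sum(tp) / n
  pe <- sum(rs * cs) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  mcc_num <- n * sum(tp) - sum(rs * cs)
  mcc_den <- sqrt(n^2 - sum(cs^2)) * sqrt(n^2 - sum(rs^2))
  mcc <- if (mcc_den > 0) mcc_num / mcc_den else 0
  auc_m <- auc_w <- NA_real_
  if (!is.null(scores) && !is.null(truth)) {
    aucs <- vapply(seq_len(k), function(cl) {
      resp <- as.integer(truth == cl)
      if (length(unique(resp)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, cl], quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }, numeric(1))
    auc_m <- mean(aucs, na.rm = TRUE)
    auc_w <- stats::weighted.mean(aucs, wts, na.rm = TRUE)
  }
  structure(list(acc = acc, auc = auc_m, auc_w = auc_w, mcc = mcc,
                 kappa = kappa,
                 f1_m = mean(f1), pre_m = mean(prec), recall_m = mean(rec),
                 f1_w = sum(wts * f1), pre_w = sum(wts * prec),
                 recall_w = sum(wts * rec),
                 per_class = data.frame(precision = prec, recall = rec,
                                        f1 = f1, support = rs),
                 cm = cm, n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric report (n = %d)\n", x$n))
  for (nm in c("acc", "auc", "mcc", "kappa", "f1_m", "pre_m", "recall_m",
               "f1_w", "pre_w", "recall_w"))
    cat(sprintf("  %-9s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  invisible(x)
}

block_mean <- function(m, f) {
  if (f == 1L) return(m)
  H <- nrow(m); W <- ncol(m)
  m <- matrix(colMeans(matrix(m, nrow = f)), nrow = H %/% f)     # rows
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = W %/% f))    # cols
}

# read patches listed in a manifest into a (3, S, S, N) tensor, block-mean
# downsampled to `size`, scaled to [-0.5, 0.5]
load_patch_tensor <- function(paths, size) {
  N <- length(paths)
  xb <- array(0, c(3L, size, size, N))
  for (i in seq_len(N)) {
    img <- read_image(paths[i])
    f <- nrow(img) %/% size
    if (f * size != nrow(img))
      stop("patch size ", nrow(img), " is not a multiple of input size ", size)
    for (ch in 1:3)
      xb[ch, , , i] <- block_mean(img[, , ch], f) / 255 - 0.5
  }
  xb
}

grade_levels <- c("low", "intermediate", "high")

train_tiny <- function(model, xb, labels, cfg, verbose = FALSE) {
  N <- dim(xb)[4L]
  state <- adamw_init()
  nb <- ceiling(N / cfg$batch_size)
  for (ep in seq_len(cfg$epochs)) {
    set.seed(cfg$seed + 7919L * ep)
    ord <- sample.int(N)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, N)]
      lr <- if (ep <= cfg$warmup_epochs)
        lr_at_epoch(0L, cfg, frac = ((ep - 1L) * nb + b) /
                      (cfg$warmup_epochs * nb))
      else lr_at_epoch(ep, cfg)
      fwd <- nn_forward(model, xb[, , , idx, drop = FALSE], training = TRUE,
                        keep = TRUE)
      model <- fwd$model
      ce <- softmax_ce(fwd$logits, labels[idx])
      ep_loss <- ep_loss + ce$loss * length(idx)
      bk <- nn_backward(model, fwd$caches, ce$dlogits)
      st <- adamw_step(model, bk$grads, state, lr, cfg$weight_decay)
      model <- st$model; state <- st$state
    }
    if (verbose)
      message(sprintf("epoch %d/%d loss %.4f", ep, cfg$epochs, ep_loss / N))
  }
  model
}

eval_tiny <- function(model, xb, labels, k) {
  N <- dim(xb)[4L]
  probs <- matrix(0, N, k)
  bs <- 32L
  for (b in seq_len(ceiling(N / bs))) {
    idx <- ((b - 1L) * bs + 1L):min(b * bs, N)
    fwd <- nn_forward(model, xb[, , , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- t(softmax_cols(fwd$logits))
  }
  pred <- max.col(probs, ties.method = "first")
  compute_metrics(confusion_matrix(labels, pred, k), probs, labels)
}

#' Train and evaluate under case-level cross-validation
#'
#' For every fold: train a freshly initialised model on the patches of all
#' other folds and evaluate on the held-out fold. Case-level leakage
#' (a case id in both train and validation) aborts with a diagnostic.
#' QC-failing patches are excluded.
#'
#' @param patches patch manifest (from [preprocess_cases()]): columns
#'   `patch_path`, `case_id`, `grade`, `fold`, `qc_pass`.
#' @param cfg a [train_config()].
#' @param model_builder function(seed) returning a fresh [tiny_cnn()].
#' @param verbose print per-epoch losses.
#' @return list with `folds` (per-fold `metric_report`s), `summary` (data
#'   frame of per-metric mean and sample sd across folds), and `models`.
#' @export
train_one_config <- function(patches, cfg = smoke_config(),
                             model_builder = function(seed)
                               tiny_cnn(input_size = cfg$input_size,
                                        seed = seed),
                             verbose = FALSE) {
  patches <- patches[patches$qc_pass, , drop = FALSE]
  if (nrow(patches) == 0L) stop("no QC-passing patches")
  folds <- sort(unique(patches$fold))
  labels <- match(patches$grade, grade_levels)
  if (anyNA(labels)) stop("grades must be low/intermediate/high")
  k <- length(grade_levels)
  for (f in folds) {
    leak <- intersect(patches$case_id[patches$fold == f],
                      patches$case_id[patches$fold != f])
    if (length(leak) > 0L)
      stop("case-level leakage: case(s) ", paste(leak, collapse = ", "),
           " appear in fold ", f, " and elsewhere")
  }
  xb <- load_patch_tensor(patches$patch_path, cfg$input_size)
  reports <- list(); models <- list()
  for (f in folds) {
    tr <- which(patches$fold != f)
    va <- which(patches$fold == f)
    # per-channel standardisation with training-fold statistics only
    xs <- xb
    stats <- matrix(0, 3L, 2L, dimnames = list(NULL, c("mean", "sd")))
    for (ch in 1:3) {
      v <- xb[ch, , , tr]
      stats[ch, ] <- c(mean(v), stats::sd(v))
      xs[ch, , , ] <- (xb[ch, , , ] - stats[ch, 1L]) / stats[ch, 2L]
    }
    model <- model_builder(cfg$seed + f)
    model <- train_tiny(model, xs[, , , tr, drop = FALSE], labels[tr], cfg,
                        verbose)
    model$norm_stats <- stats
    reports[[as.character(f)]] <-
      eval_tiny(model, xs[, , , va, drop = FALSE], labels[va], k)
    models[[as.character(f)]] <- model
  }
  nums <- c("acc", "auc", "auc_w", "mcc", "kappa", "f1_m", "pre_m",
            "recall_m", "f1_w", "pre_w", "recall_w")
  vals <- sapply(nums, function(nm)
    vapply(reports, function(r) r[[nm]], numeric(1)))
  summary <- data.frame(metric = nums,
                        mean = colMeans(vals),
                        sd = apply(vals, 2L, stats::sd))
  rownames(summary) <- NULL
  list(folds = reports, summary = summary, models = models)
}
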