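# Learning-rate schedule, metric closed forms and oracle agreement, and
# the cross-validation trainer's bookkeeping.

test_that("the schedule warms up to the base rate and anneals to zero", {
  cfg <- train_config()  # published recipe: lr 1e-4, 200 epochs
  expect_equal(lr_at_epoch(1, cfg), 1e-4)
  expect_equal(lr_at_epoch(200, cfg), 0)
  lrs <- vapply(1:200, lr_at_epoch, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  # warmup ramps linearly within epoch 0
  expect_equal(lr_at_epoch(0, cfg, frac = 0.25), 2.5e-5)
  # cosine symmetry: exact midpoint is half the base rate
  cfg201 <- train_config(epochs = 201)
  expect_equal(lr_at_epoch(101, cfg201), 5e-5)
  expect_error(lr_at_epoch(201, cfg), "outside")
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(epochs = 0), "warmup")
})

test_that("kappa matches the worked two-class arithmetic", {
  cm <- matrix(c(5, 2, 1, 4), 2)  # rows truth: [[5,1],[2,4]]
  r <- compute_metrics(cm)
  expect_equal(r$acc, 0.75)          # p_o
  expect_equal(r$kappa, 0.5)         # (0.75 - 0.5) / (1 - 0.5)
})

test_that("perfect prediction saturates every metric", {
  r <- compute_metrics(diag(c(10, 10, 10)))
  expect_equal(r$acc, 1)
  expect_equal(r$mcc, 1)
  expect_equal(r$kappa, 1)
  expect_equal(r$f1_m, 1)
  expect_equal(r$f1_w, 1)
  expect_equal(r$pre_m, 1)
  expect_equal(r$recall_w, 1)
})

test_that("constant prediction on balanced classes scores chance accuracy", {
  truth <- rep(1:3, each = 10)
  pred <- rep(1L, 30)
  r <- compute_metrics(confusion_matrix(truth, pred, 3))
  expect_equal(r$acc, 1 / 3)
  expect_equal(r$kappa, 0)
  expect_equal(r$mcc, 0)
})

test_that("metrics stay in their ranges over random confusion matrices", {
  set.seed(33)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    cm <- matrix(rpois(k * k, 3), k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    r <- suppressWarnings(compute_metrics(cm))
    expect_true(r$acc >= 0 && r$acc <= 1)
    expect_true(r$mcc >= -1 - 1e-12 && r$mcc <= 1 + 1e-12)
    expect_true(r$kappa >= -1 - 1e-12 && r$kappa <= 1 + 1e-12)
    for (nm in c("f1_m", "pre_m", "recall_m", "f1_w", "pre_w", "recall_w"))
      expect_true(r[[nm]] >= 0 && r[[nm]] <= 1)
  }
})

test_that("MCC and kappa agree with independent references", {
  skip_if_not_installed("caret")
  set.seed(44)
  for (i in 1:200) {
    lc <- rand_labels_cm(n = sample(20:60, 1), k = 3)
    r <- suppressWarnings(compute_metrics(lc$cm))
    expect_equal(r$mcc, mcc_indicator(lc$truth, lc$pred, 3),
                 tolerance = 1e-10)
    cc <- caret::confusionMatrix(
      factor(lc$pred, levels = 1:3), factor(lc$truth, levels = 1:3))
    expect_equal(r$kappa, unname(cc$overall["Kappa"]), tolerance = 1e-10)
    expect_equal(r$acc, unname(cc$overall["Accuracy"]), tolerance = 1e-10)
  }
})

test_that("macro equals weighted averaging on balanced confusion matrices", {
  set.seed(55)
  base <- matrix(rpois(9, 4), 3)
  cm <- base
  cm[] <- 0
  # force equal row sums while keeping arbitrary structure
  for (r_ in 1:3) cm[r_, ] <- rmultinom(1, 12, prob = rep(1, 3))
  r <- compute_metrics(cm)
  expect_identical(r$f1_m, r$f1_w)
  expect_identical(r$pre_m, r$pre_w)
  expect_identical(r$recall_m, r$recall_w)
})

test_that("zero-support classes warn and score zero", {
  cm <- matrix(c(5, 0, 3, 0, 0, 0, 1, 0, 6), 3)
  expect_warning(r <- compute_metrics(cm), "zero support")
  expect_equal(r$per_class$recall[2], 0)
  expect_error(compute_metrics(matrix(0, 2, 2)), "empty")
})

test_that("AUC is computed one-vs-rest on scores", {
  set.seed(66)
  truth <- rep(1:3, each = 20)
  scores <- matrix(runif(180), 60, 3)
  scores[cbind(seq_len(60), truth)] <- scores[cbind(seq_len(60), truth)] + 2
  pred <- max.col(scores)
  r <- compute_metrics(confusion_matrix(truth, pred, 3), scores, truth)
  expect_gt(r$auc, 0.95)   # near-separable scores
  expect_gt(r$auc_w, 0.95)
  r2 <- compute_metrics(confusion_matrix(truth, pred, 3))
  expect_true(is.na(r2$auc))
})

test_that("case-level leakage aborts the cross-validation trainer", {
  pm <- data.frame(patch_path = "x.png", case_id = c("a", "a", "b", "b"),
                   grade = "low", fold = c(1, 2, 1, 2), qc_pass = TRUE)
  expect_error(train_one_config(pm, smoke_config()), "leakage")
  pm0 <- pm[0, ]
  expect_error(train_one_config(pm0, smoke_config()), "no QC-passing")
})

test_that("training is reproducible under a fixed seed", {
  set.seed(1)
  N <- 24
  xb <- array(rnorm(3 * 16 * 16 * N, sd = 0.2), c(3, 16, 16, N))
  labels <- rep(1:3, length.out = N)
  for (n in seq_len(N)) xb[labels[n], , , n] <- xb[labels[n], , , n] + 0.2
  cfg <- train_config(batch_size = 8, input_size = 16, lr = 1e-2,
                      epochs = 3, seed = 5)
  m1 <- dieagrade:::train_tiny(tiny_cnn(input_size = 16, seed = 2), xb,
                               labels, cfg)
  m2 <- dieagrade:::train_tiny(tiny_cnn(input_size = 16, seed = 2), xb,
                               labels, cfg)
  f1 <- nn_forward(m1, xb)$logits
  f2 <- nn_forward(m2, xb)$logits
  expect_identical(f1, f2)
})

test_that("the trainer reduces the loss on a separable toy problem", {
  set.seed(9)
  N <- 30
  xb <- array(rnorm(3 * 16 * 16 * N, sd = 0.1), c(3, 16, 16, N))
  labels <- rep(1:3, each = 10)
  for (n in seq_len(N)) xb[labels[n], , , n] <- xb[labels[n], , , n] + 0.3
  cfg <- train_config(batch_size = 10, input_size = 16, lr = 1e-2,
                      epochs = 8, seed = 3)
  m <- dieagrade:::train_tiny(tiny_cnn(input_size = 16, seed = 7), xb,
                              labels, cfg)
  r <- dieagrade:::eval_tiny(m, xb, labels, 3)
  expect_gt(r$acc, 0.9)
})
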