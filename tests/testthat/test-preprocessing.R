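# Optical density, stain estimation/normalization, cropping, blank-patch
# QC and case-level fold assignment.

test_that("optical density maps white to zero and inverts cleanly", {
  white <- array(255, c(2, 2, 3))
  expect_equal(rgb_to_od(white), array(0, c(2, 2, 3)))
  expect_equal(rgb_to_od(array(25.5, c(1, 1, 3))),
               array(1, c(1, 1, 3)))  # -log10(25.5/255) = 1 per channel
  set.seed(3)
  img <- array(sample(1:255, 300, replace = TRUE), c(10, 10, 3))
  expect_equal(od_to_rgb(rgb_to_od(img)), img)
  expect_error(rgb_to_od(matrix(1, 3, 3)), "RGB")
})

test_that("blank fraction implements the more-than-75% removal rule", {
  expect_equal(blank_fraction(array(255, c(8, 8, 3))), 1)
  expect_false(qc_pass(1))
  expect_equal(blank_fraction(array(40, c(8, 8, 3))), 0)
  expect_true(qc_pass(0))
  # boundary: exactly 75% white passes, 76% fails
  patch <- array(40, c(20, 20, 3))
  white_px <- seq_len(300)  # 300 / 400 = 75%
  for (ch in 1:3) patch[cbind((white_px - 1) %% 20 + 1,
                              (white_px - 1) %/% 20 + 1, ch)] <- 255
  expect_equal(blank_fraction(patch), 0.75)
  expect_true(qc_pass(blank_fraction(patch)))
  white_px <- seq_len(304)  # 76%
  for (ch in 1:3) patch[cbind((white_px - 1) %% 20 + 1,
                              (white_px - 1) %/% 20 + 1, ch)] <- 255
  expect_equal(blank_fraction(patch), 0.76)
  expect_false(qc_pass(blank_fraction(patch)))
  # the QC rule is exactly blank_fraction <= 0.75
  for (bf in runif(20)) expect_identical(qc_pass(bf), bf <= 0.75)
})

test_that("random crops are reproducible, sized and bounded", {
  set.seed(1)
  img <- array(runif(300 * 320 * 3, 0, 255), c(300, 320, 3))
  c1 <- random_crops(img, n = 3, size = 256, seed = 42)
  c2 <- random_crops(img, n = 3, size = 256, seed = 42)
  expect_identical(c1, c2)
  expect_true(all(vapply(c1, function(p) all(dim(p) == c(256, 256, 3)),
                         logical(1))))
  # degenerate range: source equals crop size -> unique offset (0, 0)
  cs <- random_crops(img[1:256, 1:256, , drop = FALSE], n = 3, seed = 7)
  for (p in cs) expect_equal(attr(p, "offset"), c(0L, 0L))
  expect_error(random_crops(img[1:100, , , drop = FALSE], size = 256),
               "smaller")
})

test_that("full-size source images yield standard 256px patches", {
  img <- array(200, c(1665, 1393, 3))  # clinical scan geometry
  ps <- random_crops(img, n = 3, size = 256, seed = 9)
  expect_length(ps, 3)
  for (p in ps) expect_equal(dim(p), c(256L, 256L, 3L))
})

test_that("fold assignment is stratified, leakage-free and deterministic", {
  cases <- data.frame(
    case_id = sprintf("c%03d", 1:107),
    grade = rep(c("low", "intermediate", "high"), c(30, 38, 39)))
  f1 <- assign_folds(cases, k = 5, seed = 3)
  f2 <- assign_folds(cases, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_false(anyDuplicated(f1$case_id) > 0)
  sizes <- table(f1$grade, f1$fold)
  expect_true(all(apply(sizes, 1, function(s) diff(range(s)) <= 1)))
  expect_equal(sort(unique(f1$fold)), 1:5)
  few <- cases[c(1:3, 31:40, 69:80), ]
  expect_error(assign_folds(few, k = 5), "fewer cases")
  dup <- rbind(cases, data.frame(case_id = "c001", grade = "high"))
  expect_error(assign_folds(dup, k = 5), "more than one grade")
})

test_that("a known stain basis is recovered from synthetic tissue", {
  truth <- dieagrade:::he_reference_basis()
  img <- synth_image("intermediate", synth_spec(), seed = 31)
  b <- estimate_stain_basis(img)
  expect_equal(unname(colSums(b$W^2)), c(1, 1), tolerance = 1e-6)
  expect_gt(sum(b$W[, 1] * truth[, 1]), 0.99)
  expect_gt(sum(b$W[, 2] * truth[, 2]), 0.99)
  expect_false(b$degenerate)
  # hematoxylin ordered first: larger red-OD component
  expect_gt(b$W[1, 1], b$W[1, 2])
})

test_that("single-stain images yield a flagged degenerate basis", {
  set.seed(5)
  W <- dieagrade:::he_reference_basis()
  conc <- matrix(runif(128 * 128, 0.2, 1.2), 128, 128)
  od <- array(0, c(128, 128, 3))
  for (ch in 1:3) od[, , ch] <- W[ch, 2] * conc   # eosin only
  img <- od_to_rgb(od)
  expect_warning(b <- estimate_stain_basis(img), "degenerate")
  expect_true(b$degenerate)
})

test_that("near-blank images are rejected as insufficient tissue", {
  expect_error(estimate_stain_basis(array(255, c(100, 100, 3))),
               "insufficient tissue")
})

test_that("normalization is idempotent and preserves background", {
  img <- synth_image("high", synth_spec(), seed = 13)
  b <- estimate_stain_basis(img)
  out <- normalize_stain(img, b, b)
  expect_lte(max(abs(out - img)), 2)
  white <- array(255, c(8, 8, 3))
  expect_lte(max(abs(normalize_stain(white, b, b) - 255)), 2)
})

test_that("normalization shrinks color differences between two sources", {
  W2 <- cbind(c(0.55, 0.72, 0.42), c(0.20, 0.91, 0.16))
  W2 <- sweep(W2, 2, sqrt(colSums(W2^2)), "/")
  i1 <- synth_image("intermediate", synth_spec(), seed = 41)
  i2 <- synth_image("intermediate", synth_spec(stain_basis = W2), seed = 42)
  b1 <- estimate_stain_basis(i1); b2 <- estimate_stain_basis(i2)
  d_before <- mean(abs(apply(rgb_to_od(i1), 3, mean) -
                       apply(rgb_to_od(i2), 3, mean)))
  n2 <- normalize_stain(i2, b2, b1)
  d_after <- mean(abs(apply(rgb_to_od(i1), 3, mean) -
                      apply(rgb_to_od(n2), 3, mean)))
  expect_lt(d_after, d_before)
})

test_that("normalization halves the color spread of a mixed batch", {
  set.seed(19)
  imgs <- lapply(1:10, function(i) {
    Wr <- abs(dieagrade:::he_reference_basis() +
                matrix(runif(6, -0.12, 0.12), 3, 2))
    Wr <- sweep(Wr, 2, sqrt(colSums(Wr^2)), "/")
    synth_image("intermediate", synth_spec(stain_basis = Wr), seed = 500 + i)
  })
  bases <- lapply(imgs, estimate_stain_basis)
  normed <- lapply(seq_along(imgs), function(i)
    normalize_stain(imgs[[i]], bases[[i]], bases[[1]]))
  expect_lt(od_color_spread(normed), 0.5 * od_color_spread(imgs))
})

test_that("the preprocessing pipeline writes a QC-annotated manifest", {
  out <- withr::local_tempdir()
  mf <- synth_dataset(synth_spec(n_cases_per_grade = 5, images_per_case = 2,
                                 image_size = c(300, 300), seed = 2),
                      file.path(out, "raw"))
  pm <- preprocess_cases(mf, file.path(out, "patches"), crops = 2,
                         size = 256, seed = 11, normalize = FALSE)
  expect_equal(nrow(pm), nrow(mf) * 2)
  expect_named(pm, c("patch_path", "case_id", "grade", "fold",
                     "blank_fraction", "qc_pass"))
  expect_true(all(file.exists(pm$patch_path)))
  expect_identical(pm$qc_pass, pm$blank_fraction <= 0.75)
  # every patch of a case carries a single fold
  expect_true(all(tapply(pm$fold, pm$case_id,
                         function(v) length(unique(v))) == 1))
  expect_true(file.exists(file.path(out, "patches", "patches.csv")))
})
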