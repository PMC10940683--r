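# Patch extraction, blank-patch quality control and case-level fold
# assignment. A "case" is one patient; all patches derived from a case stay
# in one cross-validation fold (leakage-free splitting).

#' Read an image file as an 8-bit RGB array
#'
#' @param path PNG or JPEG file.
#' @return numeric `(H, W, 3)` array of intensities in 0..255.
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.jpe?g$", path, ignore.case = TRUE))
    jpeg::readJPEG(path)
  else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB array as PNG
#'
#' @param img numeric `(H, W, 3)` array (0..255).
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Extract random fixed-size crops from an image
#'
#' Crop offsets are drawn uniformly over all valid positions; the draw is
#' reproducible under `seed`.
#'
#' @param img numeric `(H, W, 3)` array.
#' @param n number of crops.
#' @param size crop side length in pixels.
#' @param seed integer seed.
#' @return list of `(size, size, 3)` arrays, each carrying an `offset`
#'   attribute (0-based row/col of the crop origin).
#' @export
random_crops <- function(img, n = 3L, size = 256L, seed = 1L) {
  assert_rgb8(img)
  d <- dim(img)
  if (d[1L] < size || d[2L] < size)
    stop("image (", d[1L], " x ", d[2L], ") is smaller than the crop size ",
         size)
  set.seed(seed)
  oy <- sample.int(d[1L] - size + 1L, n, replace = TRUE) - 1L
  ox <- sample.int(d[2L] - size + 1L, n, replace = TRUE) - 1L
  lapply(seq_len(n), function(i) {
    crop <- img[oy[i] + seq_len(size), ox[i] + seq_len(size), , drop = FALSE]
    attr(crop, "offset") <- c(oy[i], ox[i])
    crop
  })
}

#' Fraction of blank (near-white) pixels in a patch
#'
#' A pixel is blank iff all three channels are at or above
#' `white_threshold`. A patch passes quality control iff its blank fraction
#' is at most 0.75 (patches with blank parts accounting for more than 75%
#' of the area are removed).
#'
#' @param patch numeric `(H, W, 3)` array (0..255).
#' @param white_threshold intensity at or above which a channel counts as
#'   white.
#' @return blank fraction in `[0, 1]`.
#' @export
blank_fraction <- function(patch, white_threshold = 220) {
  assert_rgb8(patch, "patch")
  mean(pmin(patch[, , 1L], patch[, , 2L], patch[, , 3L]) >= white_threshold)
}

#' Blank-fraction quality-control rule
#'
#' @param bf blank fraction from [blank_fraction()].
#' @param max_blank removal boundary (strictly more than this fails).
#' @return logical: `TRUE` iff the patch is kept.
#' @export
qc_pass <- function(bf, max_blank = 0.75) bf <= max_blank

#' Assign cases to stratified cross-validation folds
#'
#' Cases are shuffled within each grade and dealt round-robin into `k`
#' folds, so per-grade fold sizes differ by at most one and every patch of
#' a case inherits a single fold.
#'
#' @param cases data frame with columns `case_id` and `grade`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return data frame `case_id`, `grade`, `fold` (fold ids `1..k`).
#' @export
assign_folds <- function(cases, k = 5L, seed = 1L) {
  stopifnot(all(c("case_id", "grade") %in% names(cases)))
  cases <- unique(cases[, c("case_id", "grade")])
  if (anyDuplicated(cases$case_id))
    stop("a case_id appears with more than one grade")
  tab <- table(cases$grade)
  if (any(tab < k))
    stop("grade(s) ", paste(names(tab)[tab < k], collapse = ", "),
         " have fewer cases than folds (k = ", k, ")")
  set.seed(seed)
  out <- lapply(split(cases, cases$grade), function(g) {
    g <- g[sample.int(nrow(g)), , drop = FALSE]
    g$fold <- rep_len(seq_len(k), nrow(g))
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full preprocessing pipeline over a case manifest
#'
#' For every source image: estimate its stain basis, normalize to the
#' target basis (the first image whose basis estimation succeeds, unless a
#' `target_image` is given), extract `crops` random crops, score each
#' crop's blank fraction, and write QC-annotated patches plus a manifest
#' CSV (`patch_path`, `case_id`, `grade`, `fold`, `blank_fraction`,
#' `qc_pass`).
#'
#' @param manifest data frame with columns `case_id`, `grade`,
#'   `image_path`.
#' @param out_dir output directory for patches and `patches.csv`.
#' @param crops crops per source image.
#' @param size patch side length.
#' @param seed master seed (fold assignment and per-image crop seeds derive
#'   from it).
#' @param k number of folds.
#' @param normalize apply stain normalization (disable for speed in
#'   pre-normalized data).
#' @param target_image optional path of the normalization reference image.
#' @return the patch manifest data frame (invisibly also written as CSV).
#' @export
preprocess_cases <- function(manifest, out_dir, crops = 3L, size = 256L,
                             seed = 17L, k = 5L, normalize = TRUE,
                             target_image = NULL) {
  stopifnot(all(c("case_id", "grade", "image_path") %in% names(manifest)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  folds <- assign_folds(manifest, k = k, seed = seed)
  fold_of <- stats::setNames(folds$fold, folds$case_id)
  target <- NULL
  if (normalize && !is.null(target_image))
    target <- estimate_stain_basis(read_image(target_image), seed = seed)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(manifest$image_path[i])
    if (normalize) {
      src <- tryCatch(estimate_stain_basis(img, seed = seed + i),
                      error = function(e) NULL)
      if (!is.null(src)) {
        if (is.null(target)) target <- src
        img <- normalize_stain(img, src, target)
      }
    }
    patches <- random_crops(img, n = crops, size = size, seed = seed + 1000L * i)
    for (j in seq_along(patches)) {
      bf <- blank_fraction(patches[[j]])
      stem <- sub("\\.[^.]+$", "", basename(manifest$image_path[i]))
      path <- file.path(out_dir, sprintf("%s_crop%d.png", stem, j))
      write_image(patches[[j]], path)
      rows[[length(rows) + 1L]] <- data.frame(
        patch_path = path,
        case_id = manifest$case_id[i],
        grade = manifest$grade[i],
        fold = unname(fold_of[manifest$case_id[i]]),
        blank_fraction = bf,
        qc_pass = qc_pass(bf),
        stringsAsFactors = FALSE)
    }
  }
  pm <- do.call(rbind, rows)
  utils::write.csv(pm, file.path(out_dir, "patches.csv"), row.names = FALSE)
  pm
}
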