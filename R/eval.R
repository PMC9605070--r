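#' Segmentation overlap metrics
#'
#' Dice coefficient `2|A&B| / (|A| + |B|)` and Jaccard/IoU `|A&B| / |A|B|`;
#' the two are related by `iou = dice / (2 - dice)`. Two empty masks score 1
#' under both metrics (a correct prediction of absence), which matters for
#' vessel-free slabs in slab-wise scoring.
#'
#' @param a,b binary masks: [label_volume()]s or arrays of equal shape.
#' @return a fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as_array3(a); b <- as_array3(b)
  if (!all(dim(a) == dim(b)))
    stop("mask shapes differ: (", paste(dim(a), collapse = ","), ") vs (",
         paste(dim(b), collapse = ","), ")")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' @rdname dice
#' @export
iou <- function(a, b) {
  a <- as_array3(a); b <- as_array3(b)
  if (!all(dim(a) == dim(b)))
    stop("mask shapes differ: (", paste(dim(a), collapse = ","), ") vs (",
         paste(dim(b), collapse = ","), ")")
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Slab-wise Dice scores
#'
#' Splits both masks into `n_slabs` contiguous, equal, non-overlapping slabs
#' along one axis and scores each slab independently — e.g. a 720-wide volume
#' gives nine 80-wide slabs. Useful to enlarge the sample for hypothesis
#' tests when only a few test volumes exist. The attached `confusion`
#' attribute holds per-slab TP/FP/FN/TN counts, which sum to the whole-volume
#' confusion counts.
#'
#' @param pred,gt binary masks of equal shape.
#' @param n_slabs number of slabs; the axis extent must divide evenly.
#' @param axis axis to split (1 = sagittal/width).
#' @return numeric vector of per-slab Dice with attribute `confusion`
#'   (`n_slabs` x 4 matrix).
#' @export
slab_scores <- function(pred, gt, n_slabs = 9L, axis = 1L) {
  pred <- as_array3(pred); gt <- as_array3(gt)
  stopifnot(all(dim(pred) == dim(gt)))
  ext <- dim(pred)[axis]
  if (ext %% n_slabs != 0L)
    stop("axis ", axis, " extent ", ext, " is not divisible into ",
         n_slabs, " equal slabs")
  wslab <- ext %/% n_slabs
  scores <- numeric(n_slabs)
  conf <- matrix(0, n_slabs, 4,
                 dimnames = list(NULL, c("tp", "fp", "fn", "tn")))
  for (s in seq_len(n_slabs)) {
    ix <- (s - 1L) * wslab + seq_len(wslab)
    ps <- switch(axis, pred[ix, , , drop = FALSE],
                 pred[, ix, , drop = FALSE], pred[, , ix, drop = FALSE])
    gs <- switch(axis, gt[ix, , , drop = FALSE],
                 gt[, ix, , drop = FALSE], gt[, , ix, drop = FALSE])
    scores[s] <- dice(ps, gs)
    tp <- sum(ps * gs)
    conf[s, ] <- c(tp, sum(ps) - tp, sum(gs) - tp,
                   length(ps) - sum(ps) - sum(gs) + tp)
  }
  attr(scores, "confusion") <- conf
  scores
}

#' Independent two-sample t-test on score lists
#'
#' Classical pooled-variance Student's t-test by default (`var_equal =
#' FALSE` gives Welch's). Two identical zero-variance groups return
#' `t = 0, p = 1` by convention rather than erroring.
#'
#' @param a,b numeric score vectors, each of length >= 2.
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return list with `t` and two-sided `p`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Relative improvement in percent
#'
#' `100 * (new - old) / old`, reported to two decimals, e.g. for comparing
#' Dice scores (on the 0-100 scale) of two models.
#'
#' @param new,old scalar scores; `old` must be positive.
#' @return percent improvement, rounded to 2 decimals.
#' @export
percent_improvement <- function(new, old) {
  if (old <= 0) stop("baseline score must be positive")
  round(100 * (new - old) / old, 2)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum along one axis, the standard 2D overview of
#' angiographic volumes; on a binary mask it is the logical OR along the
#' axis. An optional region of interest (list of per-axis index ranges)
#' restricts the projection.
#'
#' @param v a [volume()], [label_volume()] or 3D array.
#' @param axis projection axis (1-3).
#' @param roi optional list of three index vectors.
#' @return 2D matrix of the remaining two axes, in order.
#' @export
mip <- function(v, axis = 3L, roi = NULL) {
  arr <- as_array3(v)
  if (!is.null(roi)) arr <- arr[roi[[1]], roi[[2]], roi[[3]], drop = FALSE]
  apply(arr, setdiff(1:3, axis), max)
}

#' MIP-space error overlay
#'
#' Projects prediction and ground truth with [mip()] and colours the result:
#' false negatives (truth without prediction) red, false positives
#' (prediction without truth) blue, agreement white, background black.
#'
#' @param pred,gt binary masks of equal shape.
#' @param axis projection axis.
#' @param roi optional region of interest, as in [mip()].
#' @return an `h x w x 3` RGB array in \[0, 1\].
#' @export
overlay_errors <- function(pred, gt, axis = 3L, roi = NULL) {
  pred <- as_array3(pred); gt <- as_array3(gt)
  if (!all(dim(pred) == dim(gt)))
    stop("mask shapes differ")
  pm <- mip(pred, axis, roi) > 0
  gm <- mip(gt, axis, roi) > 0
  d <- dim(pm)
  rgb <- array(0, c(d, 3L))
  rgb[, , 1][gm] <- 1                 # red channel: all truth
  rgb[, , 3][pm & !gm] <- 1           # blue: false positive
  rgb[, , 2][pm & gm] <- 1            # agreement -> white
  rgb[, , 3][pm & gm] <- 1
  rgb
}

#' Write an RGB overlay as PNG
#' @param rgb array from [overlay_errors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(rgb, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG overlays")
  png::writePNG(aperm(rgb, c(2, 1, 3)), path)
  invisible(path)
}

#' Full metric report for one prediction
#'
#' @param pred,gt binary masks of equal shape.
#' @param n_slabs slabs for [slab_scores()]; skipped (NULL) if the axis does
#'   not divide evenly.
#' @param axis slab axis.
#' @param volume_id,model_id free-text metadata carried into the report.
#' @return a `metric_report` list: `dice`, `iou` (fractions), `dice_pct`
#'   (x100, 2 decimals), per-slab Dice, metadata.
#' @export
metric_report <- function(pred, gt, n_slabs = 9L, axis = 1L,
                          volume_id = NA_character_,
                          model_id = NA_character_) {
  d <- dice(pred, gt)
  slabs <- NULL
  if (!is.null(n_slabs) && dim(as_array3(pred))[axis] %% n_slabs == 0L)
    slabs <- slab_scores(pred, gt, n_slabs, axis)
  structure(list(dice = d, iou = iou(pred, gt),
                 dice_pct = round(100 * d, 2), slab_dice = as.numeric(slabs),
                 volume_id = volume_id, model_id = model_id),
            class = "metric_report")
}
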