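mk_mask <- function(v, d = c(4, 4, 4)) array(v, d)

test_that("Dice and IoU match hand counts and conventions", {
  a <- mk_mask(0); a[1, 1, 1] <- 1; a[2, 1, 1] <- 1
  b <- mk_mask(0); b[1, 1, 1] <- 1; b[3, 1, 1] <- 1
  expect_equal(dice(a, b), 0.5)     # |A|=|B|=2, overlap 1
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  z <- mk_mask(0)
  expect_equal(dice(z, z), 1)       # both empty -> correct absence
  expect_equal(iou(z, z), 1)
  d1 <- mk_mask(0); d1[1, , ] <- 1
  d2 <- mk_mask(0); d2[4, , ] <- 1
  expect_equal(dice(d1, d2), 0)
  expect_error(dice(a, array(0, c(5, 5, 5))), "differ")
})

test_that("IoU = Dice/(2 - Dice) and symmetry hold on random masks", {
  set.seed(40)
  for (i in 1:100) {
    a <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
    b <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
    d <- dice(a, b)
    expect_equal(iou(a, b), d / (2 - d), tolerance = 1e-12)
    expect_equal(d, dice(b, a))
    expect_equal(iou(a, b), iou(b, a))
  }
})

test_that("slab scoring splits evenly and conserves confusion counts", {
  set.seed(41)
  d <- c(18L, 6L, 6L)
  pred <- array(sample(0:1, prod(d), TRUE, prob = c(0.8, 0.2)), d)
  gt <- array(sample(0:1, prod(d), TRUE, prob = c(0.8, 0.2)), d)
  s <- slab_scores(pred, gt, n_slabs = 9, axis = 1)
  expect_length(s, 9)
  conf <- attr(s, "confusion")
  tp <- sum(pred * gt)
  expect_equal(colSums(conf),
               c(tp = tp, fp = sum(pred) - tp, fn = sum(gt) - tp,
                 tn = prod(d) - sum(pred) - sum(gt) + tp))
  expect_equal(as.numeric(slab_scores(gt, gt, 9, 1)), rep(1, 9))
  # masks confined to opposite end slabs: ends score 0, empty middles 1
  p1 <- array(0, d); p1[1:2, , ] <- 1
  g9 <- array(0, d); g9[17:18, , ] <- 1
  expect_equal(as.numeric(slab_scores(p1, g9, 9, 1)),
               c(0, rep(1, 7), 0))
  expect_error(slab_scores(pred[1:17, , ], gt[1:17, , ], 9, 1),
               "divisible")
})

test_that("pooled t-test matches the textbook formula and conventions", {
  # worked example, hand-computable: equal variances, n = 3 each
  a <- c(10, 12, 14); b <- c(20, 22, 24)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4          # pooled variance, df = 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), df = 4, lower.tail = FALSE)
  res <- two_sample_ttest(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  # identical groups
  expect_equal(two_sample_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(two_sample_ttest(c(0, 0, 0, 0), c(0, 0, 0, 0))$p, 1)
  # nearly separated groups -> tiny p
  set.seed(42)
  res2 <- two_sample_ttest(rnorm(4, 0, 1e-4), 1 + rnorm(4, 0, 1e-4))
  expect_lt(res2$p, 1e-6)
  # Welch flavour available
  res3 <- two_sample_ttest(a, c(b, 40), var_equal = FALSE)
  expect_true(is.finite(res3$t))
})

test_that("percent improvement reproduces simple ratios", {
  expect_equal(percent_improvement(110, 100), 10)
  expect_equal(percent_improvement(50, 50), 0)
  expect_equal(percent_improvement(79.44, 76.19), 4.27)
  expect_error(percent_improvement(1, 0), "positive")
})

test_that("MIP projects maxima and ORs binary masks", {
  v <- array(0, c(4, 5, 6))
  v[2, 3, 4] <- 0.7
  m <- mip(v, axis = 3)
  expect_equal(dim(m), c(4, 5))
  expect_equal(m[2, 3], 0.7)
  expect_equal(sum(m > 0), 1)
  set.seed(43)
  mask <- array(sample(0:1, 120, TRUE), c(4, 5, 6))
  expect_equal(mip(mask, axis = 1),
               apply(mask, c(2, 3), function(z) as.numeric(any(z > 0))))
  # ROI-restricted projection
  roi <- list(1:2, 1:5, 1:6)
  expect_equal(dim(mip(v, axis = 3, roi = roi)), c(2, 5))
  expect_equal(max(mip(v, axis = 3, roi = roi)), 0.7)
})

test_that("error overlays colour FN red, FP blue, TP white", {
  gt <- array(0, c(6, 6, 3)); gt[2:3, 2:3, ] <- 1
  pred <- array(0, c(6, 6, 3)); pred[3:4, 2:3, ] <- 1
  rgb <- overlay_errors(pred, gt, axis = 3)
  pm <- mip(pred, 3) > 0; gm <- mip(gt, 3) > 0
  red_only <- rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0
  blue_only <- rgb[, , 3] == 1 & rgb[, , 1] == 0 & rgb[, , 2] == 0
  white <- rgb[, , 1] == 1 & rgb[, , 2] == 1 & rgb[, , 3] == 1
  expect_equal(sum(red_only), sum(gm & !pm))
  expect_equal(sum(blue_only), sum(pm & !gm))
  expect_equal(sum(white), sum(pm & gm))
  # perfect prediction: no red-only, no blue pixels
  rgb2 <- overlay_errors(gt, gt, axis = 3)
  expect_equal(sum(rgb2[, , 1] != rgb2[, , 3]), 0)
  # empty prediction: red only
  rgb3 <- overlay_errors(array(0, dim(gt)), gt, axis = 3)
  expect_equal(sum(rgb3[, , 3]), 0)
  expect_gt(sum(rgb3[, , 1]), 0)
  skip_if_not_installed("png")
  path <- tempfile(fileext = ".png")
  write_overlay_png(rgb, path)
  expect_true(file.size(path) > 0)
})

test_that("metric reports carry consistent summaries", {
  set.seed(44)
  pred <- array(sample(0:1, 18 * 4 * 4, TRUE), c(18, 4, 4))
  gt <- array(sample(0:1, 18 * 4 * 4, TRUE), c(18, 4, 4))
  r <- metric_report(pred, gt, n_slabs = 9, axis = 1, volume_id = "v1")
  expect_equal(r$iou, r$dice / (2 - r$dice), tolerance = 1e-12)
  expect_equal(r$dice_pct, round(100 * r$dice, 2))
  expect_length(r$slab_dice, 9)
})
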