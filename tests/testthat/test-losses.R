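shape_vec <- function(v) array(v, c(length(v), 1, 1))

test_that("Tversky index matches hand-counted confusion terms", {
  p <- tversky_params(alpha = 0.7, beta = 0.75, gamma = 1, epsilon = 1e-6)
  pred <- shape_vec(c(1, 1, 0, 0))
  target <- shape_vec(c(1, 0, 1, 0))
  # TP = 1, FN = 1, FP = 1
  expect_equal(tversky_index(pred, target, p),
               (1 + 1e-6) / (1 + 0.7 + 0.75 + 1e-6), tolerance = 1e-12)
  # perfect binary prediction -> TI = 1 exactly
  expect_equal(tversky_index(target, target, p), 1)
  # all-zero prediction vs n foreground voxels -> eps / (alpha n + eps)
  for (n in c(4, 64)) {
    z <- array(0, c(n, 1, 1)); o <- array(1, c(n, 1, 1))
    expect_equal(tversky_index(z, o, p), 1e-6 / (0.7 * n + 1e-6),
                 tolerance = 1e-12)
  }
  expect_error(tversky_index(shape_vec(c(1, 0)), target), "does not match")
})

test_that("focal Tversky loss follows (1-TI)^(1/gamma)", {
  p1 <- tversky_params(gamma = 1, epsilon = 1e-6)
  pred <- shape_vec(c(1, 1, 0, 0)); target <- shape_vec(c(1, 0, 1, 0))
  ti <- tversky_index(pred, target, p1)
  expect_equal(focal_tversky_loss(pred, target, p1), 1 - ti,
               tolerance = 1e-12)
  expect_equal(focal_tversky_loss(target, target, p1), 0)
  # TI = 0.75 with gamma = 2 -> sqrt(0.25) = 0.5 (synthetic TI via soft pred)
  p2 <- tversky_params(alpha = 0.5, beta = 0.5, gamma = 2, epsilon = 1e-9)
  # soft pred p on all-ones target: TI = p/(p + 0.5(1-p)); p = 0.6 -> 0.75
  pred2 <- array(0.6, c(10, 1, 1)); tgt2 <- array(1, c(10, 1, 1))
  expect_equal(tversky_index(pred2, tgt2, p2), 0.75, tolerance = 1e-6)
  expect_equal(focal_tversky_loss(pred2, tgt2, p2), 0.5, tolerance = 1e-4)
})

test_that("focal loss is monotone decreasing in TI for gamma in [1,3]", {
  for (g in c(1, 4 / 3, 2, 3)) {
    ti <- seq(0.01, 0.99, by = 0.01)
    ftl <- (1 - ti)^(1 / g)
    expect_true(all(diff(ftl) < 0))
  }
})

test_that("Tversky with alpha=beta=0.5 equals smoothed Dice", {
  set.seed(20)
  p <- tversky_params(alpha = 0.5, beta = 0.5, epsilon = 1e-6)
  for (i in 1:50) {
    a <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
    b <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
    smoothed_dice <- (2 * sum(a * b) + 2e-6) / (sum(a) + sum(b) + 2e-6)
    expect_equal(tversky_index(a, b, p), smoothed_dice, tolerance = 1e-12)
    expect_gt(tversky_index(a, b, p), 0)
    expect_lte(tversky_index(a, b, p), 1)
  }
})

test_that("MSS loss is the normalised weighted mean of per-tap losses", {
  set.seed(21)
  p <- tversky_params()
  target <- array(sample(0:1, 8^3, TRUE, prob = c(0.9, 0.1)), c(8, 8, 8))
  maps <- lapply(1:3, function(i) array(runif(8^3), c(8, 8, 8)))
  w <- mss_weights(c(1, 0.5, 0.25))
  per_tap <- vapply(maps, focal_tversky_loss, 0, target = target, p = p)
  expect_equal(mss_loss(maps, target, w, p),
               sum(w$alphas * per_tap) / sum(w$alphas), tolerance = 1e-12)
  # single map degenerates to plain focal Tversky loss
  expect_equal(mss_loss(maps[1], target, mss_weights(1), p), per_tap[1])
  # rescaling all weights is a no-op
  expect_equal(mss_loss(maps, target, mss_weights(10 * w$alphas), p),
               mss_loss(maps, target, w, p), tolerance = 1e-12)
  # equal weights -> arithmetic mean
  expect_equal(mss_loss(maps, target, mss_weights(c(1, 1, 1)), p),
               mean(per_tap), tolerance = 1e-12)
  expect_error(mss_loss(maps[1:2], target, w, p), "weights")
})

test_that("supervised loss sums the two branch losses", {
  set.seed(22)
  p <- tversky_params(); w <- mss_weights()
  y <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  ty <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  out1 <- lapply(1:3, function(i) array(runif(64), c(4, 4, 4)))
  out2 <- lapply(1:3, function(i) array(runif(64), c(4, 4, 4)))
  expect_equal(supervised_loss(out1, y, out2, ty, w, p),
               mss_loss(out1, y, w, p) + mss_loss(out2, ty, w, p),
               tolerance = 1e-12)
  # both branches perfect -> 0
  bin <- lapply(1:3, function(i) y)
  expect_equal(supervised_loss(bin, y, bin, y, w, p), 0)
})

test_that("consistency loss vanishes for equivariant binary predictions", {
  set.seed(23)
  p <- tversky_params()
  shape <- c(16L, 16L, 16L)
  x <- array(0, shape); x[5:12, 5:12, 5:12] <- 1
  # identity transform, deterministic "network": pred == target -> 0
  t0 <- sample_elastic_transform(shape, 5, max_displacement = 0)
  out <- list(x, x, x)
  expect_equal(consistency_loss(out, out, t0, p), 0)
  # exactly equivariant identity predictor, nearest-mode warp, any t
  for (i in 1:5) {
    t1 <- sample_elastic_transform(shape)
    y1 <- x                              # f(x) = x
    y2 <- warp(x, t1$field, "nearest")   # f(t(x)) = t(x)
    c0 <- focal_tversky_loss(y2, warp(y1, t1$field, "nearest"), p)
    expect_equal(c0, 0)
  }
  # all-zero prediction pair -> 0 (both sums empty, TI = 1)
  z <- array(0, shape)
  expect_equal(consistency_loss(list(z), list(z), t0, p), 0)
})

test_that("total loss is the unit-weighted sum", {
  expect_equal(total_loss(0.8, 0.1), 0.9)
  expect_equal(total_loss(0, 0), 0)
})

test_that("loss gradients match numerical differentiation", {
  set.seed(24)
  p <- tversky_params()
  pred <- array(runif(64, 0.05, 0.95), c(4, 4, 4))
  target <- array(runif(64), c(4, 4, 4))
  g <- deformseg:::ftl_grad(pred, target, p)
  eps <- 1e-6
  for (idx in sample(64, 20)) {
    pp <- pred; pp[idx] <- pp[idx] + eps
    pm <- pred; pm[idx] <- pm[idx] - eps
    num <- (focal_tversky_loss(pp, target, p) -
            focal_tversky_loss(pm, target, p)) / (2 * eps)
    expect_lt(abs(num - g$dpred[idx]), 1e-4)
    tp <- target; tp[idx] <- tp[idx] + eps
    tm <- target; tm[idx] <- tm[idx] - eps
    numt <- (focal_tversky_loss(pred, tp, p) -
             focal_tversky_loss(pred, tm, p)) / (2 * eps)
    expect_lt(abs(numt - g$dtarget[idx]), 1e-4)
  }
})
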