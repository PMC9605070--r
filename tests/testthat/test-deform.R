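test_that("control grid sampling respects bounds, locking and seeds", {
  set.seed(1)
  g0 <- sample_control_grid(c(16, 16, 16), max_displacement = 0)
  expect_true(all(g0$displacements == 0))
  set.seed(2)
  g <- sample_control_grid(c(16, 16, 16), n_points_choices = 5L,
                           locked_border = 2L)
  expect_equal(g$n_points, 5L)
  # 5 - 2*2 = 1 free control point per axis
  free <- which(apply(g$displacements != 0, 1:3, any))
  expect_lte(length(free), 1)
  expect_true(all(g$displacements[c(1, 2, 4, 5), , , ] == 0))
  expect_true(all(abs(g$displacements) <= 0.02))
  set.seed(3); ga <- sample_control_grid(c(16, 16, 16))
  set.seed(3); gb <- sample_control_grid(c(16, 16, 16))
  expect_identical(ga, gb)
  # n drawn from {5,6,7}
  set.seed(4)
  ns <- replicate(50, sample_control_grid(c(16, 16, 16))$n_points)
  expect_true(all(ns %in% 5:7))
  expect_gt(length(unique(ns)), 1)
})

test_that("densify matches brute-force kernel summation", {
  set.seed(5)
  for (n in c(5L, 6L, 7L)) {
    shape <- c(10L, 12L, 16L)
    g <- sample_control_grid(shape, n_points_choices = n, locked_border = 1L)
    expect_lt(max(abs(densify(g, shape) - bspline_kernel_oracle(g, shape))),
              1e-6)
  }
})

test_that("densify degenerate and partition-of-unity cases", {
  g0 <- sample_control_grid(c(12, 12, 12), 5, max_displacement = 0)
  expect_true(all(densify(g0, c(12, 12, 12)) == 0))
  # ungated constant grid: interior displacement equals the constant
  # (interior = voxels at least two control spacings from the boundary,
  # where the B-spline kernels form a partition of unity)
  g <- sample_control_grid(c(16, 16, 16), 9, locked_border = 0L)
  d0 <- 0.01
  g$displacements[] <- d0
  f <- densify(g, c(16, 16, 16))
  h <- 2 / 8                      # control spacing for n = 9
  interior <- which(abs(-1 + (2 * seq_len(16) - 1) / 16) <= 1 - 2 * h)
  expect_gt(length(interior), 0)
  expect_lt(max(abs(f[interior, interior, interior, ] - d0 * 16 / 2)), 1e-6)
  # re-densifying reproduces the field exactly
  expect_identical(f, densify(g, c(16, 16, 16)))
})

test_that("warp handles identity, shifts and value sets", {
  img <- array(seq_len(8^3), c(8, 8, 8))
  zf <- array(0, c(8, 8, 8, 3))
  expect_equal(warp(img, zf), img)
  # uniform +1 voxel along x: out(x) = in(x+1), last column reads 0
  sf <- zf; sf[, , , 1] <- 1
  out <- warp(img, sf)
  expect_equal(out[1:7, , ], img[2:8, , ])
  expect_true(all(out[8, , ] == 0))
  # nearest mode preserves the binary value set
  ball <- array(0, c(8, 8, 8))
  ball[3:6, 3:6, 3:6] <- 1
  set.seed(6)
  t1 <- sample_elastic_transform(c(8, 8, 8), 5, 0.05, 1)
  expect_true(all(warp(ball, t1$field, "nearest") %in% c(0, 1)))
  expect_error(warp(ball, array(0, c(4, 4, 4, 3))), "does not match")
})

test_that("trilinear warp is linear in the image and adjoint is exact", {
  set.seed(7)
  t1 <- sample_elastic_transform(c(8, 8, 8), 6, 0.08, 1)
  u <- array(rnorm(512), c(8, 8, 8))
  v <- array(rnorm(512), c(8, 8, 8))
  expect_equal(warp(2 * u + 3 * v, t1$field),
               2 * warp(u, t1$field) + 3 * warp(v, t1$field),
               tolerance = 1e-12)
  d <- array(rnorm(512), c(8, 8, 8))
  expect_equal(sum(d * warp(u, t1$field)),
               sum(warp_backward(d, t1$field) * u), tolerance = 1e-10)
})

test_that("analytic warp gradient matches numerical differentiation", {
  set.seed(8)
  t1 <- sample_elastic_transform(c(8, 8, 8), 5, 0.06, 1)
  img <- array(runif(512), c(8, 8, 8))
  # d mean(warp(img)) / d img = warp_backward(1/n) by linearity
  ana <- warp_backward(array(1 / 512, c(8, 8, 8)), t1$field)
  eps <- 1e-6
  for (idx in sample(512, 10)) {
    ip <- img; ip[idx] <- ip[idx] + eps
    im <- img; im[idx] <- im[idx] - eps
    num <- (mean(warp(ip, t1$field)) - mean(warp(im, t1$field))) / (2 * eps)
    expect_lt(abs(num - ana[idx]), 1e-4)
  }
})

test_that("transform pairs keep labels binary and nearly intact", {
  set.seed(9)
  shape <- c(32L, 32L, 32L)
  x <- array(runif(prod(shape)), shape)
  y <- array(1, shape)
  t0 <- sample_elastic_transform(shape, 5, max_displacement = 0)
  pair0 <- apply_transform_pair(t0, x, y)
  expect_equal(pair0$x, x)
  expect_equal(pair0$y, y)
  t1 <- sample_elastic_transform(shape, 7, 0.02, 2)
  pair1 <- apply_transform_pair(t1, x, y)
  expect_true(all(pair1$y %in% c(0, 1)))
  # all-ones label stays all-ones away from a 2-voxel border rim
  inner <- 3:30
  expect_true(all(pair1$y[inner, inner, inner] == 1))
})

test_that("label volume fraction is stable under sampled transforms", {
  set.seed(10)
  shape <- c(64L, 64L, 64L)
  y <- array(0, shape)
  y[16:48, 16:48, 16:48] <- 1
  x <- y
  frac <- mean(y)
  for (i in 1:100) {
    t1 <- sample_elastic_transform(shape)
    ty <- apply_transform_pair(t1, x, y)$y
    expect_lt(abs(mean(ty) - frac) / frac, 0.05)
  }
})

test_that("transforms serialise with enough information to re-densify", {
  set.seed(11)
  t1 <- sample_elastic_transform(c(16, 16, 16))
  j <- jsonlite::fromJSON(transform_json(t1))
  g2 <- structure(list(n_points = j$n_points,
                       displacements = array(j$displacements,
                                             c(j$n_points, j$n_points,
                                               j$n_points, 3)),
                       max_displacement = j$max_displacement,
                       locked_border = j$locked_border),
                  class = "control_grid")
  expect_equal(densify(g2, c(16, 16, 16)), t1$field,
               tolerance = 1e-12, ignore_attr = TRUE)
})
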