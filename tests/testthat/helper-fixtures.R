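# Shared tiny fixtures, all generated in code.

tiny_phantom_spec <- function(seed = 1L, shape = c(32L, 32L, 32L), ...) {
  args <- utils::modifyList(
    list(shape = shape, n_trees = 2L, branch_depth = 2L,
         radius_range = c(1, 2), noise_sigma = 0.03,
         bias_amplitude = 0.1, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

tiny_net <- function(base = 2L, taps = 3L, seed = 1L) {
  build_network(network_config(base_channels = base,
                               supervision_taps = taps), seed = seed)
}

# brute-force cubic B-spline kernel summation, the independent oracle for
# densify(): iterates control points explicitly and accumulates each kernel
# contribution over the whole voxel lattice (no separable contraction trick)
bspline_kernel_oracle <- function(grid, shape) {
  b3 <- function(t) {
    a <- abs(t)
    ifelse(a < 1, 2 / 3 - a^2 + a^3 / 2, ifelse(a < 2, (2 - a)^3 / 6, 0))
  }
  n <- grid$n_points
  u <- seq(-1, 1, length.out = n)
  h <- u[2] - u[1]
  coords <- lapply(shape, function(S) -1 + (2 * seq_len(S) - 1) / S)
  field <- array(0, c(shape, 3))
  for (m in 1:3) {
    acc <- array(0, shape)
    for (a in seq_len(n)) for (b in seq_len(n)) for (cc in seq_len(n)) {
      d <- grid$displacements[a, b, cc, m]
      if (d == 0) next
      ka <- b3((coords[[1]] - u[a]) / h)
      kb <- b3((coords[[2]] - u[b]) / h)
      kc <- b3((coords[[3]] - u[cc]) / h)
      acc <- acc + d * outer(outer(ka, kb), kc)
    }
    field[, , , m] <- acc * shape[m] / 2
  }
  field
}

# patch pairs from a phantom, for tiny training runs
phantom_patches <- function(spec, patch = 16L, stride = 16L,
                            corrupt = FALSE) {
  ph <- generate_phantom(spec)
  v <- normalize_minmax(add_artifacts(ph$volume, spec))
  y <- ph$label
  g <- compute_patch_origins(dim(v$data), patch, rep(stride, 3L))
  Map(function(x, yy) list(x = x, y = yy),
      extract_patches(v, g), extract_patches(y, g))
}
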