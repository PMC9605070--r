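#' Random elastic deformations via cubic B-spline control grids
#'
#' A deformation is parameterised by a coarse `n x n x n` grid of displacement
#' vectors in normalised coordinates (each axis spans \[-1, 1\], so a
#' displacement of 0.02 is 1% of the axis extent, about 0.64 voxels on a 64^3
#' patch). The per-voxel displacement field is obtained by separable cubic
#' B-spline interpolation of the grid, then converted to voxel units. The
#' outermost `locked_border` rings of control points are fixed at zero so the
#' deformation vanishes towards the patch faces.
#'
#' @name deform
NULL

# Cubic B-spline kernel, support (-2, 2), partition of unity on the integer
# lattice.
bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, 2 / 3 - a^2 + a^3 / 2,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

#' Sample a random control grid
#'
#' The number of control points per axis is drawn uniformly from
#' `n_points_choices` (default 5, 6 or 7, giving different deformation
#' scales), and every free control displacement component is drawn uniformly
#' in `[-max_displacement, max_displacement]`. Randomness comes from R's RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @param shape length-3 target image shape (voxels), all entries >= 8.
#' @param n_points_choices candidate control-point counts per axis.
#' @param max_displacement maximum |displacement| per component, in normalised
#'   coordinates.
#' @param locked_border number of outermost control-point rings fixed to zero.
#' @return a `control_grid`: list with `n_points`, `displacements`
#'   (`n x n x n x 3` array), `max_displacement`, `locked_border`.
#' @export
sample_control_grid <- function(shape, n_points_choices = c(5L, 6L, 7L),
                                max_displacement = 0.02, locked_border = 2L) {
  stopifnot(length(shape) == 3L, all(shape >= 8))
  n <- if (length(n_points_choices) == 1L) as.integer(n_points_choices)
       else as.integer(sample(n_points_choices, 1L))
  d <- array(runif(n^3 * 3, -max_displacement, max_displacement),
             dim = c(n, n, n, 3L))
  if (locked_border > 0L) {
    lb <- seq_len(locked_border)
    ring <- c(lb, n + 1L - lb)
    free <- setdiff(seq_len(n), ring)
    mask <- array(0, dim = c(n, n, n))
    if (length(free) > 0L) mask[free, free, free] <- 1
    for (m in 1:3) d[, , , m] <- d[, , , m] * mask
  }
  structure(list(n_points = n, displacements = d,
                 max_displacement = max_displacement,
                 locked_border = as.integer(locked_border)),
            class = "control_grid")
}

# n x n control points evenly spaced over \[-1, 1\]; voxel centres at
# -1 + (2i+1)/S for 0-based i.
control_locations <- function(n) seq(-1, 1, length.out = n)

voxel_coords_norm <- function(S) -1 + (2 * seq_len(S) - 1) / S

# mode-1 tensor contraction helpers for the separable kernel sum
mode_contract <- function(D3, B) {
  # D3: (n, n, n); B: (S, n); returns (S, n, n) contracting the first mode
  n <- dim(D3)[1]
  out <- B %*% matrix(D3, nrow = n)
  array(out, dim = c(nrow(B), dim(D3)[2], dim(D3)[3]))
}

#' Densify a control grid to a per-voxel displacement field
#'
#' Evaluates `field(v) = sum_c d_c * B3((v - u_c)/h)` separably per axis,
#' where `B3` is the cubic B-spline kernel, `u_c` the control locations and
#' `h` their spacing, then converts from normalised units (axis spans [-1,1])
#' to voxel units (component `a` is scaled by `shape[a] / 2`).
#'
#' @param grid a `control_grid`.
#' @param shape length-3 image shape in voxels.
#' @return a `displacement_field`: array `(W, H, D, 3)` in voxel units.
#' @export
densify <- function(grid, shape) {
  n <- grid$n_points
  u <- control_locations(n)
  h <- u[2] - u[1]
  basis <- lapply(shape, function(S) {
    v <- voxel_coords_norm(S)
    outer(v, u, function(vi, uj) bspline3((vi - uj) / h))
  })
  field <- array(0, dim = c(shape, 3L))
  for (m in 1:3) {
    t1 <- mode_contract(grid$displacements[, , , m], basis[[1]])   # (W,n,n)
    t2 <- mode_contract(aperm(t1, c(2, 1, 3)), basis[[2]])         # (H,W,n)
    t3 <- mode_contract(aperm(t2, c(3, 2, 1)), basis[[3]])         # (D,W,H)
    field[, , , m] <- aperm(t3, c(2, 3, 1)) * (shape[m] / 2)
  }
  class(field) <- c("displacement_field", class(field))
  field
}

#' Backward warp of a 3D image by a displacement field
#'
#' Computes `out(x, y, z) = img(x + dx, y + dy, z + dz)` with the chosen
#' interpolation; sample positions outside the volume read 0 (air
#' background). Trilinear mode is linear in `img`, so consistency-loss
#' gradients can flow through the warp via [warp_backward()].
#'
#' @param img 3D array.
#' @param field displacement field `(W, H, D, 3)` in voxel units.
#' @param mode `"trilinear"` or `"nearest"`.
#' @return warped 3D array.
#' @export
warp <- function(img, field, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(img)
  if (length(d) != 3L || !all(dim(field)[1:3] == d))
    stop("image shape (", paste(d, collapse = ","),
         ") does not match field shape (",
         paste(dim(field)[1:3], collapse = ","), ")")
  out <- cpp_warp_fwd(as.double(img), as.integer(d), as.double(field),
                      mode == "nearest")
  array(out, dim = d)
}

#' Adjoint of the trilinear warp with respect to the image
#'
#' @param dout gradient array at the warp output.
#' @param field the displacement field used in the forward warp.
#' @return gradient array with respect to the warp input image.
#' @export
warp_backward <- function(dout, field) {
  d <- dim(dout)
  array(cpp_warp_bwd(as.double(dout), as.integer(d), as.double(field)),
        dim = d)
}

#' Sample a full elastic transform for a given image shape
#'
#' Bundles a random control grid with its densified field. Re-densifying the
#' stored grid reproduces the field exactly.
#'
#' @inheritParams sample_control_grid
#' @return an `elastic_transform`: list with `grid`, `field`, `shape`.
#' @export
sample_elastic_transform <- function(shape, n_points_choices = c(5L, 6L, 7L),
                                     max_displacement = 0.02,
                                     locked_border = 2L) {
  grid <- sample_control_grid(shape, n_points_choices, max_displacement,
                              locked_border)
  structure(list(grid = grid, field = densify(grid, shape),
                 shape = as.integer(shape)),
            class = "elastic_transform")
}

#' Apply an elastic transform to an image/label pair
#'
#' The image is warped with trilinear interpolation; the label is warped
#' trilinearly and re-binarised at 0.5 so the supervised branch keeps binary
#' targets. (The consistency branch instead warps soft predictions directly
#' with [warp()], without thresholding, so gradients flow.)
#'
#' @param t an `elastic_transform`.
#' @param x image patch (3D array).
#' @param y label patch (3D array, binary).
#' @return list with warped `x` and re-binarised `y`.
#' @export
apply_transform_pair <- function(t, x, y) {
  stopifnot(all(dim(x) == dim(y)), all(dim(x) == t$shape))
  list(x = warp(x, t$field, "trilinear"),
       y = (warp(y, t$field, "trilinear") >= 0.5) * 1)
}

#' Serialize an elastic transform's parameters to JSON
#' @param t an `elastic_transform`.
#' @return a JSON string with `n_points`, `max_displacement`, `locked_border`
#'   and the raw control displacements (sufficient to re-densify).
#' @export
transform_json <- function(t) {
  g <- t$grid
  jsonlite::toJSON(list(n_points = g$n_points,
                        max_displacement = g$max_displacement,
                        locked_border = g$locked_border,
                        shape = t$shape,
                        displacements = as.vector(g$displacements)),
                   auto_unbox = TRUE, digits = NA)
}
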