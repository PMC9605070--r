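#' Deterministic 3D patch grids
#'
#' Computes the ordered set of patch origins for an isotropic cubic patch and
#' per-axis strides. Per axis the origins are `0, s, 2s, ..., k*s` with
#' `k = floor((shape - patch_size) / s)`; with `cover_ends = TRUE` the extra
#' origin `shape - patch_size` is appended when the regular grid stops short,
#' so that stitched inference covers every voxel. Origins are 0-based and the
#' grid is the lexicographically sorted Cartesian product.
#'
#' @param shape integer length-3 volume shape (width, height, depth).
#' @param patch_size isotropic patch edge length in voxels.
#' @param strides integer length-3 per-axis strides.
#' @param cover_ends append end-aligned origins for full coverage (inference);
#'   leave `FALSE` to reproduce plain floor-formula training/validation grids.
#' @return a `patch_grid`: list with `patch_size`, `strides`, `volume_shape`,
#'   and `origins` (an n x 3 integer matrix of 0-based origins).
#' @examples
#' g <- compute_patch_origins(c(720, 630, 195), 64, c(32, 32, 16))
#' nrow(g$origins)  # 3402 patches per volume
#' @export
compute_patch_origins <- function(shape, patch_size, strides,
                                  cover_ends = FALSE) {
  shape <- as.integer(shape); strides <- as.integer(strides)
  patch_size <- as.integer(patch_size)
  stopifnot(length(shape) == 3L, length(strides) == 3L, all(strides >= 1L))
  for (a in 1:3)
    if (patch_size > shape[a])
      stop("patch size ", patch_size, " exceeds volume extent ", shape[a],
           " on axis ", a)
  ax <- lapply(1:3, function(a) {
    k <- (shape[a] - patch_size) %/% strides[a]
    o <- seq.int(0L, by = strides[a], length.out = k + 1L)
    last <- shape[a] - patch_size
    if (cover_ends && o[length(o)] < last) o <- c(o, last)
    o
  })
  # lexicographic order with axis 1 most significant
  grid <- expand.grid(z = ax[[3]], y = ax[[2]], x = ax[[1]],
                      KEEP.OUT.ATTRS = FALSE)
  origins <- as.matrix(grid[, c("x", "y", "z")])
  dimnames(origins) <- NULL
  structure(list(patch_size = patch_size, strides = strides,
                 volume_shape = shape, origins = origins),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d origins, patch %d^3, strides (%s), volume (%s)\n",
              nrow(x$origins), x$patch_size,
              paste(x$strides, collapse = ","),
              paste(x$volume_shape, collapse = ",")))
  invisible(x)
}

#' Serialize a patch grid to JSON (for provenance logs)
#' @param g a `patch_grid`.
#' @return a JSON string.
#' @export
patch_grid_json <- function(g) {
  jsonlite::toJSON(list(patch_size = g$patch_size, strides = g$strides,
                        volume_shape = g$volume_shape, origins = g$origins),
                   auto_unbox = TRUE)
}

as_array3 <- function(v) {
  if (inherits(v, "vol_volume")) v$data else v
}

#' Extract patches on a grid
#'
#' @param v a [volume()], [label_volume()] or bare 3D array whose shape equals
#'   `g$volume_shape`.
#' @param g a `patch_grid` from [compute_patch_origins()].
#' @return list of `patch_size^3` arrays, one per origin, in origin order.
#' @export
extract_patches <- function(v, g) {
  arr <- as_array3(v)
  if (!all(dim(arr) == g$volume_shape))
    stop("volume shape (", paste(dim(arr), collapse = ","),
         ") does not match grid shape (",
         paste(g$volume_shape, collapse = ","), ")")
  p <- g$patch_size
  lapply(seq_len(nrow(g$origins)), function(i) {
    o <- g$origins[i, ]
    arr[o[1] + 1:p, o[2] + 1:p, o[3] + 1:p, drop = FALSE]
  })
}

#' Stitch patches back into a volume
#'
#' Overlapping voxels receive the arithmetic mean of all contributing patch
#' values (the conventional variance-reducing choice for averaged sliding
#' window probabilities). Voxels covered by no patch are filled with 0 and
#' counted in the attached coverage report.
#'
#' @param patches list of arrays as returned by [extract_patches()].
#' @param g the `patch_grid` the patches were extracted with.
#' @return a 3D array of shape `g$volume_shape` with attribute `coverage`,
#'   a list with `uncovered` (voxel count) and `max_multiplicity`.
#' @export
stitch_patches <- function(patches, g) {
  if (length(patches) != nrow(g$origins))
    stop("got ", length(patches), " patches for ", nrow(g$origins), " origins")
  p <- g$patch_size
  acc <- array(0, g$volume_shape)
  cnt <- array(0L, g$volume_shape)
  for (i in seq_len(nrow(g$origins))) {
    o <- g$origins[i, ]
    ix <- o[1] + 1:p; iy <- o[2] + 1:p; iz <- o[3] + 1:p
    acc[ix, iy, iz] <- acc[ix, iy, iz] + patches[[i]]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  covered <- cnt > 0L
  acc[covered] <- acc[covered] / cnt[covered]
  attr(acc, "coverage") <- list(uncovered = sum(!covered),
                                max_multiplicity = max(cnt))
  acc
}
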