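#' Volume containers and NIfTI I/O
#'
#' A `vol_volume` holds a 3D intensity array together with its voxel spacing
#' (mm) and 4x4 voxel-to-world affine. Array axes are ordered
#' (sagittal/width, coronal/height, axial/depth); coordinates are 0-based and
#' voxel-centred. A `vol_label` is the paired binary vessel mask under the
#' same contract.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel, all positive.
#' @param affine 4x4 voxel-to-world matrix.
#' @return `volume()` returns a `vol_volume`; `label_volume()` a `vol_label`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got dimensionality ",
         if (is.array(data)) length(dim(data)) else "0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "vol_volume")
}

#' @rdname volume
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  v <- volume(data, spacing, affine)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1)))
    stop("label volume must be binary (0/1)")
  storage.mode(v$data) <- "double"
  class(v) <- c("vol_label", "vol_volume")
  v
}

#' @export
print.vol_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Axes are kept in on-disk order (width, height, depth) and the affine is
#' preserved verbatim. A trailing singleton 4th axis (as written by some
#' scanners) is squeezed with a warning; any other dimensionality is an error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    warning("squeezing singleton 4th axis of ", path)
    arr <- array(arr, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D in ", path)
  volume(arr,
         spacing = RNifti::pixdim(img)[1:3],
         affine = unclass(RNifti::xform(img)))
}

#' Read a binary label volume from NIfTI
#'
#' Values are binarised at > 0.5 on load.
#'
#' @inheritParams load_volume
#' @return a [label_volume()].
#' @export
load_labels <- function(path) {
  v <- load_volume(path)
  label_volume((v$data > 0.5) * 1, spacing = v$spacing, affine = v$affine)
}

#' Write a volume to NIfTI-1
#'
#' @param v a [volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  stopifnot(inherits(v, "vol_volume"))
  img <- RNifti::asNifti(v$data)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Min-max intensity normalisation to \[0, 1\]
#'
#' Maps a non-constant volume affinely so its minimum is 0 and maximum is 1.
#' Constant volumes (e.g. background-only patches) map to all zeros rather
#' than dividing by zero.
#'
#' @param v a [volume()].
#' @return a [volume()] with the same spacing/affine.
#' @export
normalize_minmax <- function(v) {
  stopifnot(inherits(v, "vol_volume"))
  r <- range(v$data)
  d <- if (r[2] > r[1]) (v$data - r[1]) / (r[2] - r[1]) else array(0, dim(v$data))
  out <- v
  out$data <- d
  out
}
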