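#' Inference configuration
#'
#' @param patch_size cubic patch edge used at inference; must be divisible by
#'   16 (the network downsamples 4 times). 32, 64 and 96 are the supported
#'   presets; larger patches suit lower-resolution inputs.
#' @param threshold probability cutoff for binarisation.
#' @param batch_size patches per forward pass.
#' @return an `inference_config` list.
#' @export
inference_config <- function(patch_size = 64L, threshold = 0.5,
                             batch_size = 4L) {
  if (patch_size %% 16L != 0L)
    stop("patch_size must be divisible by 16, got ", patch_size)
  stopifnot(threshold > 0, threshold < 1, batch_size >= 1)
  structure(list(patch_size = as.integer(patch_size), threshold = threshold,
                 batch_size = as.integer(batch_size)),
            class = "inference_config")
}

#' Segment a whole volume
#'
#' Tiles the volume with non-overlapping patches plus end-aligned remainder
#' patches so every voxel is covered, forwards each patch in evaluation mode
#' (full-resolution head only), stitches the probabilities back with
#' averaging in overlap regions, and thresholds. Volumes smaller than the
#' patch on any axis are zero-padded to patch size and cropped back, with a
#' warning.
#'
#' @param net a trained `msnet`.
#' @param v a [volume()], intensities already normalised to \[0, 1\]
#'   (see [normalize_minmax()]).
#' @param cfg an [inference_config()].
#' @return list with `mask` (a [label_volume()]) and `prob` (a [volume()] of
#'   foreground probabilities), both of the input's shape and affine.
#' @export
segment_volume <- function(net, v, cfg = inference_config()) {
  stopifnot(inherits(v, "vol_volume"), inherits(net, "msnet"))
  arr <- v$data
  r <- range(arr)
  if (r[1] < 0 || r[2] > 1)
    stop("volume must be normalised to [0,1] before inference; see ",
         "normalize_minmax()")
  orig_shape <- dim(arr)
  pad <- pmax(cfg$patch_size - orig_shape, 0L)
  if (any(pad > 0L)) {
    warning("volume smaller than patch on axis ", which(pad > 0L)[1],
            "; zero-padding to patch size")
    padded <- array(0, pmax(orig_shape, cfg$patch_size))
    padded[seq_len(orig_shape[1]), seq_len(orig_shape[2]),
           seq_len(orig_shape[3])] <- arr
    arr <- padded
  }
  g <- compute_patch_origins(dim(arr), cfg$patch_size,
                             rep(cfg$patch_size, 3L), cover_ends = TRUE)
  patches <- extract_patches(arr, g)
  probs <- vector("list", length(patches))
  idx <- split(seq_along(patches),
               ceiling(seq_along(patches) / cfg$batch_size))
  p <- cfg$patch_size
  for (bi in idx) {
    x5 <- array(0, c(p, p, p, 1L, length(bi)))
    for (i in seq_along(bi)) x5[, , , 1L, i] <- patches[[bi[i]]]
    out <- ms_forward(net, x5, train = FALSE, keep_cache = FALSE)
    for (i in seq_along(bi))
      probs[[bi[i]]] <- array(out$maps[[1]][, , , 1L, i], dim = c(p, p, p))
  }
  prob <- stitch_patches(probs, g)
  prob <- prob[seq_len(orig_shape[1]), seq_len(orig_shape[2]),
               seq_len(orig_shape[3]), drop = FALSE]
  dim(prob) <- orig_shape
  mask <- (prob >= cfg$threshold) * 1
  list(mask = label_volume(mask, spacing = v$spacing, affine = v$affine),
       prob = volume(prob, spacing = v$spacing, affine = v$affine))
}
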