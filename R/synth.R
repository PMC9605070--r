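#' Synthetic vascular phantom specification
#'
#' Describes a phantom emulating the qualitative appearance of time-of-flight
#' MR angiography: bright tubular trees (small vessels 1-2 voxels in
#' apparent diameter, larger trunks) on a dark background, optionally
#' corrupted by additive Gaussian noise, a smooth multiplicative bias field
#' and global sinusoidal spike interference. Trees are grown as seeded
#' random-walk centrelines with bounded curvature and per-step branching;
#' the radius tapers from `radius_range[2]` at the root to
#' `radius_range[1]` at the leaves.
#'
#' @param shape length-3 volume shape in voxels.
#' @param n_trees number of vessel trees.
#' @param branch_depth maximum branching generations.
#' @param radius_range `(min, max)` tube radius in voxels; min >= 0.5 and
#'   max at most a quarter of the smallest extent.
#' @param vessel_intensity,background_intensity tissue intensities in \[0,1\];
#'   vessel must be brighter.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param bias_amplitude relative amplitude of the low-order polynomial bias
#'   field (0 disables).
#' @param n_spikes number of sinusoidal spike artefacts.
#' @param spike_amplitude amplitude of each spike sinusoid.
#' @param curvature maximum random bending per centreline step (radians).
#' @param branch_prob per-step probability of spawning a branch.
#' @param seed RNG seed; the phantom is fully reproducible from it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), n_trees = 3L,
                         branch_depth = 3L, radius_range = c(1, 2.5),
                         vessel_intensity = 0.9,
                         background_intensity = 0.1, noise_sigma = 0.05,
                         bias_amplitude = 0.2, n_spikes = 0L,
                         spike_amplitude = 0.2, curvature = 0.25,
                         branch_prob = 0.06, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 16))
  if (vessel_intensity <= background_intensity)
    stop("vessel_intensity must exceed background_intensity")
  if (radius_range[1] < 0.5 || radius_range[2] > min(shape) / 4)
    stop("radius_range must lie within [0.5, min(shape)/4]")
  stopifnot(radius_range[1] <= radius_range[2])
  structure(list(shape = as.integer(shape), n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 radius_range = as.numeric(radius_range),
                 vessel_intensity = vessel_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 n_spikes = as.integer(n_spikes),
                 spike_amplitude = spike_amplitude, curvature = curvature,
                 branch_prob = branch_prob, seed = as.integer(seed)),
            class = "phantom_spec")
}

perturb_dir <- function(dir, curvature) {
  if (curvature <= 0) return(dir)
  v <- dir + curvature * rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic vascular phantom
#'
#' Grows `n_trees` random-walk branching centrelines, paints anti-aliased
#' spheres of tapering radius along them, and renders intensity as
#' `background + (vessel - background) * soft_occupancy` — a bright tube
#' with a smooth half-voxel boundary. The binary label is the occupancy
#' thresholded at 0.5. Identical seeds give bit-identical phantoms; each
#' tree's label is 26-connected.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume()]) and `label`
#'   (a [label_volume()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  centres <- matrix(0, 0, 3)
  radii <- numeric()
  rmin <- spec$radius_range[1]; rmax <- spec$radius_range[2]
  for (tree in seq_len(spec$n_trees)) {
    face_axis <- sample(3L, 1L)
    face_side <- sample(c(0L, 1L), 1L)
    start <- round(c(runif(1, d[1] * 0.2, d[1] * 0.8),
                     runif(1, d[2] * 0.2, d[2] * 0.8),
                     runif(1, d[3] * 0.2, d[3] * 0.8)))
    start[face_axis] <- if (face_side == 0L) 1 else d[face_axis]
    dir0 <- numeric(3)
    dir0[face_axis] <- if (face_side == 0L) 1 else -1
    dir0 <- dir0 + spec$curvature * rnorm(3)
    dir0 <- dir0 / sqrt(sum(dir0^2))
    max_len <- sum(d)  # generous cap; walks stop at the volume boundary
    queue <- list(list(pos = start, dir = dir0, radius = rmax, depth = 0L))
    while (length(queue) > 0L) {
      seg <- queue[[1]]; queue <- queue[-1]
      pos <- seg$pos; dir <- seg$dir; r <- seg$radius
      steps <- 0L
      pts <- matrix(0, max_len, 3)
      prs <- numeric(max_len)
      while (all(pos >= 1) && all(pos <= d) && steps < max_len) {
        pts[steps + 1L, ] <- pos
        prs[steps + 1L] <- r
        # taper towards the leaf radius as the walk progresses
        r <- max(rmin, r * 0.995)
        dir <- perturb_dir(dir, spec$curvature)
        pos <- pos + dir
        steps <- steps + 1L
        if (seg$depth < spec$branch_depth &&
            runif(1) < spec$branch_prob && r > rmin) {
          queue[[length(queue) + 1L]] <-
            list(pos = pos, dir = perturb_dir(dir, 1.0),
                 radius = max(rmin, r * 0.7), depth = seg$depth + 1L)
        }
      }
      if (steps > 0L) {
        centres <- rbind(centres, pts[seq_len(steps), , drop = FALSE])
        radii <- c(radii, prs[seq_len(steps)])
      }
    }
  }
  soft <- if (nrow(centres) > 0L)
    cpp_paint_spheres(centres, radii, d)
  else array(0, d)
  lab <- (soft >= 0.5) * 1
  img <- spec$background_intensity +
    (spec$vessel_intensity - spec$background_intensity) * soft
  list(volume = volume(img), label = label_volume(lab))
}

#' Add MRA-like artefacts to a normalised volume
#'
#' Adds Gaussian noise (`noise_sigma`), multiplies by a smooth random
#' second-order polynomial bias field (`1 + bias_amplitude * q`, `q`
#' normalised to \[-1, 1\]) and injects `n_spikes` global sinusoids of random
#' frequency and phase (the image-space appearance of k-space spikes). The
#' result is clipped back to \[0, 1\]. With all amplitudes zero the volume is
#' returned unchanged.
#'
#' @param v a [volume()] with data in \[0, 1\].
#' @param spec a [phantom_spec()] carrying the artefact amplitudes.
#' @return a corrupted [volume()].
#' @export
add_artifacts <- function(v, spec) {
  stopifnot(inherits(v, "vol_volume"))
  set.seed(spec$seed + 1000L)
  arr <- v$data
  d <- dim(arr)
  if (spec$bias_amplitude > 0) {
    u <- lapply(1:3, function(a) seq(-1, 1, length.out = d[a]))
    cf <- runif(9, -1, 1)
    q <- cf[1] * outer(outer(u[[1]], rep(1, d[2])), rep(1, d[3])) +
      cf[2] * outer(outer(rep(1, d[1]), u[[2]]), rep(1, d[3])) +
      cf[3] * outer(outer(rep(1, d[1]), rep(1, d[2])), u[[3]]) +
      cf[4] * outer(outer(u[[1]], u[[2]]), rep(1, d[3])) +
      cf[5] * outer(outer(u[[1]], rep(1, d[2])), u[[3]]) +
      cf[6] * outer(outer(rep(1, d[1]), u[[2]]), u[[3]]) +
      cf[7] * outer(outer(u[[1]]^2, rep(1, d[2])), rep(1, d[3])) +
      cf[8] * outer(outer(rep(1, d[1]), u[[2]]^2), rep(1, d[3])) +
      cf[9] * outer(outer(rep(1, d[1]), rep(1, d[2])), u[[3]]^2)
    q <- q / max(abs(q))
    arr <- arr * (1 + spec$bias_amplitude * q)
  }
  if (spec$noise_sigma > 0)
    arr <- arr + array(rnorm(length(arr), 0, spec$noise_sigma), d)
  if (spec$n_spikes > 0) {
    co <- lapply(1:3, function(a) (seq_len(d[a]) - 1) / d[a])
    for (s in seq_len(spec$n_spikes)) {
      k <- sample(1:8, 3, replace = TRUE)
      phase <- runif(1, 0, 2 * pi)
      wave <- sin(2 * pi * (k[1] * outer(outer(co[[1]], rep(1, d[2])),
                                         rep(1, d[3])) +
                            k[2] * outer(outer(rep(1, d[1]), co[[2]]),
                                         rep(1, d[3])) +
                            k[3] * outer(outer(rep(1, d[1]), rep(1, d[2])),
                                         co[[3]])) + phase)
      arr <- arr + spec$spike_amplitude * wave
    }
  }
  if (spec$bias_amplitude > 0 || spec$noise_sigma > 0 || spec$n_spikes > 0)
    arr <- pmin(pmax(arr, 0), 1)
  out <- v
  out$data <- array(arr, d)
  out
}

# 26-neighbourhood foreground count, via shifted copies
neighbor_count <- function(lab) {
  d <- dim(lab)
  cnt <- array(0, d)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src <- lab[pmin(pmax(seq_len(d[1]) + di, 1), d[1]),
               pmin(pmax(seq_len(d[2]) + dj, 1), d[2]),
               pmin(pmax(seq_len(d[3]) + dk, 1), d[3])]
    cnt <- cnt + src
  }
  cnt
}

#' Emulate imperfect (noisy) labels
#'
#' Degrades a clean label the way semi-automatic annotation degrades real
#' vessel labels: thin-vessel segments are dropped until about
#' `drop_fraction` of the foreground is gone (removal chunks prefer voxels
#' with few foreground neighbours, i.e. thin branches), and short gaps of
#' `gap_length` voxels are cut across remaining vessels. The output is
#' always a subset of the input.
#'
#' @param y a [label_volume()] or binary array.
#' @param drop_fraction target fraction of foreground to remove.
#' @param gap_length edge length (voxels) of the cut-out gap boxes; 0
#'   disables gaps.
#' @param seed RNG seed.
#' @return corrupted label of the same type as `y`.
#' @export
corrupt_labels <- function(y, drop_fraction = 0.3, gap_length = 0L,
                           seed = 1L) {
  lab <- as_array3(y)
  stopifnot(all(lab %in% c(0, 1)))
  set.seed(seed)
  d <- dim(lab)
  out <- lab
  if (gap_length > 0 && sum(out) > 0) {
    fg <- which(out == 1)
    n_gaps <- max(1L, length(fg) %/% 2000L)
    centres <- arrayInd(sample(fg, min(n_gaps, length(fg))), d)
    half <- gap_length %/% 2
    for (i in seq_len(nrow(centres))) {
      lo <- pmax(centres[i, ] - half, 1)
      hi <- pmin(centres[i, ] + (gap_length - 1L - half), d)
      out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 0
    }
  }
  if (drop_fraction > 0 && sum(lab) > 0) {
    target <- (1 - drop_fraction) * sum(lab)
    nb <- neighbor_count(out)
    thin <- which(out == 1 & nb <= 12)
    pool <- if (length(thin) > 0) sample(thin) else integer()
    pi_ <- 1L
    while (sum(out) > target) {
      if (pi_ > length(pool)) {
        left <- which(out == 1)
        if (length(left) == 0L) break
        pool <- sample(left)
        pi_ <- 1L
      }
      centre <- arrayInd(pool[pi_], d)[1, ]
      pi_ <- pi_ + 1L
      if (out[centre[1], centre[2], centre[3]] == 0) next
      lo <- pmax(centre - 2L, 1); hi <- pmin(centre + 2L, d)
      out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 0
    }
  }
  if (inherits(y, "vol_label"))
    label_volume(out, spacing = y$spacing, affine = y$affine)
  else out
}

#' Connected components of a binary mask (26-connectivity)
#'
#' @param mask binary 3D array or [label_volume()].
#' @return integer array of component labels (0 = background).
#' @export
connected_components <- function(mask) {
  arr <- as_array3(mask)
  cpp_conncomp26(arr > 0, as.integer(dim(arr)))
}
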