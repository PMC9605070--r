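---
title: "Deformation-aware segmentation of small vessels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-aware segmentation of small vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small cerebral vessels — apparent diameter of one to two voxels in
high-resolution time-of-flight MR angiography — are the structures whose
pathology underlies cerebral small vessel disease. Segmenting them
automatically is hard for two compounding reasons: the foreground is a tiny,
thin, elongated fraction of the volume, and the training labels that exist
in practice are produced semi-automatically, so they are noisy, contain
gaps, and miss many of the smallest vessels.

`deformseg` implements a training strategy aimed at exactly this regime:

1. a **3D U-Net with multi-scale supervision (MSS)** as backbone — an
   encoder–decoder with four max-pool downsamplings, two
   (conv 3×3×3 → batch norm → ReLU) blocks per level, trilinear upsampling
   with skip concatenation, and sigmoid 1×1×1 heads at the last three
   decoder levels. The deeper heads are resampled to label resolution with
   nearest-neighbour interpolation and each head contributes a loss term, so
   discriminative features are encouraged at every scale;
2. the **focal Tversky loss** as the per-head criterion, which weights false
   negatives and false positives separately (essential under extreme class
   imbalance);
3. a second, **Siamese deformation-consistency phase**: each patch `x` and a
   randomly elastically deformed copy `t(x)` are forwarded through the *same*
   weights; besides the supervised losses of both branches, a consistency
   term penalises the disagreement between the prediction for `t(x)` and the
   warped prediction `t(f(x))`. The network is thereby pushed to be
   *equivariant* to elastic deformation — a strong, label-free prior for
   tubular anatomy — which is what lets it keep learning from a small,
   imperfect label set.

## The losses

For foreground probability `p` and target `g` the Tversky index is

    TI = (Σ p·g + ε) / (Σ p·g + α Σ (1−p)·g + β Σ p·(1−g) + ε)

with `α = 0.7` (false-negative weight) and `β = 0.75` (false-positive
weight) as defaults. The focal Tversky loss is `FTL = (1 − TI)^(1/γ)`. The
multi-scale loss is the weighted mean `Σ αᵢ FTLᵢ / Σ αᵢ` over the heads, and
the phase-2 objective is

    L = MSS(f(x), y) + MSS(f(t(x)), t(y)) + FTL(f(t(x)), t(f(x)))

with unit weights and gradients flowing through *both* branches, including
through the warp (its adjoint is exact because the trilinear warp is linear
in the image).

Parameter choices that the original setting leaves open, and how this
package resolves them:

* **γ (focal exponent)** — defaults to 4/3, the value the focal-Tversky
  literature recommends; configurable in `[1, 3]`.
* **ε** — defaults to `1e-6`; it is a smoothing constant, not a tuning
  knob.
* **per-scale weights αᵢ** — default `(1, 0.5, 0.25)` from the output head
  downwards, emphasising the full-resolution prediction.
* **consistency at one scale** — the consistency term compares the
  full-resolution heads only; the deeper heads exist for supervision.
* **batch pooling of the Tversky sums (training only).** The exported loss
  functions compute the index per patch, as defined above. The training
  loop, however, pools the confusion sums over the whole batch before
  forming the index (the "batch Dice" convention). The reason is
  gradient-theoretic: for a background-only patch the per-patch index
  degenerates to `TI = ε/(ε + βΣp)` and its gradient is `O(ε)` —
  background-only patches then contribute essentially nothing, false
  positives in empty regions are never suppressed, and training stalls (we
  observed exactly this failure mode: training loss plateaus near 0.6 while
  the segmentation drowns in false positives). Pooling over the batch gives
  every voxel a gradient on the same scale. With large patches that contain
  vessels almost surely, the two conventions behave identically.

## The elastic deformation model

A deformation is a coarse `n×n×n` grid of displacement vectors (`n` drawn
uniformly from {5, 6, 7}, a different draw per patch per iteration)
densified to a per-voxel field by separable cubic B-spline interpolation.
Conventions:

* Control displacements live in **normalised coordinates**: each axis spans
  `[−1, 1]`, so the default maximum displacement 0.02 is 1% of the axis
  extent — about 0.64 voxels on a 64³ patch, 0.16 voxels on a 16³ patch.
  The alternative reading (0.02 voxels) would make the augmentation
  invisible; the normalised-coordinate reading matches kernel-transform
  implementations of elastic augmentation.
* The outermost **two rings of control points are locked** to zero so the
  deformation fades towards patch faces.
* Out-of-volume samples read **0** — the air background of MRA.
* In the supervised branch, warped labels are re-binarised at 0.5; the
  consistency target `t(f(x))` stays soft and is *not* gradient-stopped.

`densify()` is tested against a brute-force kernel-summation oracle
(tolerance 1e-6), the warp against shift oracles, a linearity identity, and
an adjoint/numerical-gradient check (1e-4).

## Numerical engine

No deep-learning runtime is part of this package's dependency set; the
backbone, its backpropagation, Adam, batch norm and the differentiable warp
are implemented in the package itself with compiled kernels
(im2col + BLAS GEMM convolutions, argmax-tracked max pooling, trilinear and
nearest upsampling with exact adjoints). Everything is double precision.
Backpropagation is verified against central differences at `eps = 1e-6`
(relative error ≲ 1e-6 where no ReLU kink is crossed). Determinism: all
randomness flows through R's RNG, so a fixed seed reproduces weights,
patch orders, transforms and loss curves bit-for-bit on a fixed BLAS.

Memory note: the classic width (`base_channels = 64`) at 64³ patches is a
GPU-scale configuration; on CPU use the tiny preset (`base_channels = 8`)
and 16³–32³ patches, which is what all shipped tests use.

## The synthetic phantom generator

Real 7T TOF-MRA with reliable labels is not redistributable, so the package
ships a generator that emulates the *qualitative* properties that matter
for this method:

* **geometry** — seeded random-walk branching trees with bounded curvature;
  radius tapers towards the leaves down to ~1 voxel, so "small vessels"
  (1–2 voxel diameter) genuinely occur; labels are the 0.5 level set of an
  anti-aliased tube occupancy, and each tree is 26-connected;
* **appearance** — bright tubes (default intensity 0.9) on dark background
  (0.1), additive Gaussian noise (default σ = 0.05), a smooth multiplicative
  second-order polynomial bias field (default ±20%), and optional global
  sinusoids emulating k-space spike artefacts;
* **label imperfection** — `corrupt_labels()` removes thin-branch chunks
  until a target fraction of the foreground is gone and cuts short gaps,
  mimicking semi-automatic annotations (which score only ~0.5 Dice against
  careful manual labels on real data).

What the phantoms deliberately do **not** model: MR physics (no inflow or
Bloch simulation), vessel-adjacent tissue contrast, motion artefacts, or
anatomically realistic vascular topology. Passing the phantom-based
end-to-end test therefore demonstrates that the machinery — patching,
losses, two-phase optimisation, equivariance training, inference,
evaluation — works as designed, *not* that the shipped defaults reach any
particular accuracy on clinical MRA.

## Scaled-down study conditions

The end-to-end surface (tests and `scripts/acceptance.R`) runs the full
two-phase pipeline at desk scale, with these frozen choices:

* eight 96³ phantoms with default appearance parameters (fixed seeds
  101–108), split 6 train / 1 validation / 1 test;
* training patches 16³ on a stride-16 grid (1296 train patches), batch 8,
  96 patches per epoch drawn uniformly without replacement;
* `base_channels = 8`; Adam, learning rate 0.01 (both phases); 10 supervised
  epochs, then 5 deformation-aware epochs; checkpoint = lowest validation
  loss (supervised MSS loss in both phases, so the phases are comparable);
* inference with non-overlapping, end-covered 16³ patches, threshold 0.5.

With these conditions the held-out phantom Dice is typically ≈ 0.9 after the
supervised phase, and the deformation-aware phase does not degrade it (in
our runs it improves slightly). The real-data headline numbers of the
7T study (Dice ~0.80 against semi-automatic labels) require the restricted
dataset and GPU-scale training and are out of scope here; the phantom
surface is a property check, not a reproduction.

Patch-extraction bookkeeping, in contrast, is checked *exactly*: a
720×630×195 volume tiled with 64³ patches at strides (32, 32, 16) yields
3402 patches, hence 20 412 for six training volumes and 6804 for two
validation volumes. The nine-slab evaluation (80×630×195 slabs along the
sagittal axis) and the pooled two-sample t-test on slab Dice scores are
implemented as published; for 96³ phantoms the acceptance script uses eight
slabs of twelve voxels, since 96 does not divide into nine.

## Degenerate inputs and tie-breaks

* Constant volumes min-max normalise to all zeros (background-only patches
  exist; dividing by zero would poison them).
* Two empty masks score Dice = IoU = 1 — a correct prediction of absence —
  which matters for vessel-free slabs.
* Zero-variance identical groups give `p = 1` in the t-test rather than an
  error.
* Checkpoint ties resolve to the earliest epoch.
* Max-pool argmax ties resolve to the first voxel in scan order.
* Volumes smaller than the inference patch are zero-padded and cropped
  back, with a warning.
* The binarisation threshold defaults to 0.5 (not stated in the original
  setting; exposed in `inference_config()`).

## Known limitations

* CPU-only and double precision: the faithful 64-channel configuration at
  64³ patches is impractical here; the package targets method correctness
  and desk-scale experiments.
* The phantom generator's realism is qualitative (see above).
* Uniform patch sampling only — vessel-biased sampling is deliberately out
  of scope.
* Batch norm statistics are shared between the Siamese branches within a
  step (both branches run in training mode over the same underlying
  patches), which is the standard shared-weights reading of the design.
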