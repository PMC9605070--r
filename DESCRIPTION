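Package: deformseg
Title: Deformation-Aware Semi-Supervised Segmentation of Small Vessels in 3D Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based 3D segmentation of small blood vessels in time-of-flight
    MR angiography volumes. Implements a modified U-Net with multi-scale (deep)
    supervision trained with the focal Tversky loss, and a Siamese
    deformation-consistency objective in which a random cubic B-spline elastic
    deformation is applied to the input and the network is penalised when its
    prediction is not equivariant to that deformation. Includes NIfTI volume I/O,
    deterministic overlapping patch extraction and averaging stitch-back,
    whole-volume inference at several patch sizes, Dice/IoU/slab-wise evaluation
    with maximum-intensity-projection error overlays, and a synthetic vascular
    phantom generator (tubular trees, noise, bias fields, spike artefacts, noisy
    labels) so that the full pipeline can be exercised at desk scale on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    oro.nifti,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
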