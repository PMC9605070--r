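#' Tversky / focal Tversky parameters
#'
#' `alpha` weights false negatives, `beta` false positives (the asymmetric
#' generalisation of Dice, which is `alpha = beta = 0.5`); `gamma` in \[1, 3\]
#' is the focal exponent and `epsilon` a smoothing constant guarding empty
#' masks. Defaults follow the vessel-segmentation setting: alpha 0.7,
#' beta 0.75; gamma defaults to 4/3, the value the focal-Tversky literature
#' recommends.
#'
#' @param alpha false-negative weight, >= 0.
#' @param beta false-positive weight, >= 0.
#' @param gamma focal exponent in \[1, 3\].
#' @param epsilon smoothing constant, > 0.
#' @return a `tversky_params` list.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.75, gamma = 4 / 3,
                           epsilon = 1e-6) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 1, gamma <= 3, epsilon > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 epsilon = epsilon), class = "tversky_params")
}

#' Per-scale weights for multi-scale supervision
#'
#' One positive weight per supervision tap, full-resolution head first. The
#' aggregate loss is normalised by the weight sum, so rescaling all weights
#' leaves it unchanged. Default (1, 0.5, 0.25) emphasises the output head.
#'
#' @param alphas positive numeric vector of per-scale weights.
#' @return an `mss_weights` list.
#' @export
mss_weights <- function(alphas = c(1, 0.5, 0.25)) {
  stopifnot(all(alphas > 0))
  structure(list(alphas = as.numeric(alphas)), class = "mss_weights")
}

check_pair <- function(pred, target) {
  if (!all(dim(pred) == dim(target)) || length(pred) != length(target))
    stop("prediction shape (", paste(dim(pred), collapse = ","),
         ") does not match target shape (",
         paste(dim(target), collapse = ","), ")")
}

#' Tversky index
#'
#' `TI = (sum(p*g) + eps) / (sum(p*g) + alpha*sum((1-p)*g) +
#' beta*sum(p*(1-g)) + eps)` for the single foreground (vessel) class; the
#' background class is implicit through `1 - p`. Equals the smoothed Dice
#' overlap when `alpha = beta = 0.5`.
#'
#' @param pred array of foreground probabilities in \[0, 1\].
#' @param target array of targets in \[0, 1\] (binary labels, or soft targets
#'   in the consistency objective).
#' @param p a [tversky_params()].
#' @return scalar in (0, 1].
#' @export
tversky_index <- function(pred, target, p = tversky_params()) {
  check_pair(pred, target)
  tp <- sum(pred * target)
  fn <- sum((1 - pred) * target)
  fp <- sum(pred * (1 - target))
  (tp + p$epsilon) / (tp + p$alpha * fn + p$beta * fp + p$epsilon)
}

#' Focal Tversky loss
#'
#' `FTL = (1 - TI)^(1/gamma)`; zero for a perfect prediction, monotone
#' decreasing in the Tversky index for every gamma in \[1, 3\].
#'
#' @inheritParams tversky_index
#' @return scalar in \[0, 1\].
#' @export
focal_tversky_loss <- function(pred, target, p = tversky_params()) {
  (1 - tversky_index(pred, target, p))^(1 / p$gamma)
}

# Loss value plus analytic gradients w.r.t. both arguments (the consistency
# objective needs d/dtarget because its target is a warped network output).
ftl_grad <- function(pred, target, p = tversky_params()) {
  check_pair(pred, target)
  tp <- sum(pred * target)
  fn <- sum((1 - pred) * target)
  fp <- sum(pred * (1 - target))
  num <- tp + p$epsilon
  den <- tp + p$alpha * fn + p$beta * fp + p$epsilon
  ti <- num / den
  loss <- (1 - ti)^(1 / p$gamma)
  base <- max(1 - ti, 1e-12)
  dl_dti <- -(1 / p$gamma) * base^(1 / p$gamma - 1)
  ab <- 1 - p$alpha - p$beta
  dti_dpred <- (target * den - num * (target * ab + p$beta)) / den^2
  dti_dtarget <- (pred * den - num * (pred * ab + p$alpha)) / den^2
  list(loss = loss,
       dpred = dl_dti * dti_dpred,
       dtarget = dl_dti * dti_dtarget)
}

#' Multi-scale supervision loss
#'
#' Weighted mean of the per-tap focal Tversky losses:
#' `sum(alpha_i * FTL_i) / sum(alpha_i)`, every tap compared with the same
#' full-resolution label.
#'
#' @param out a `multiscale_output` (see [forward()]) or plain list of
#'   probability maps, full-resolution head first.
#' @param target label array of the maps' shape.
#' @param w an [mss_weights()] of the same length as `out`.
#' @param p a [tversky_params()].
#' @return scalar loss.
#' @export
mss_loss <- function(out, target, w = mss_weights(), p = tversky_params()) {
  maps <- if (inherits(out, "multiscale_output")) out$maps else out
  if (length(maps) != length(w$alphas))
    stop("got ", length(maps), " maps for ", length(w$alphas), " weights")
  num <- sum(vapply(seq_along(maps), function(i)
    w$alphas[i] * focal_tversky_loss(maps[[i]], target, p), 0))
  num / sum(w$alphas)
}

mss_grad <- function(maps, target, w = mss_weights(), p = tversky_params()) {
  stopifnot(length(maps) == length(w$alphas))
  s <- sum(w$alphas)
  loss <- 0
  dmaps <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    g <- ftl_grad(maps[[i]], target, p)
    loss <- loss + w$alphas[i] * g$loss / s
    dmaps[[i]] <- (w$alphas[i] / s) * g$dpred
  }
  list(loss = loss, dmaps = dmaps)
}

#' Supervised loss of the Siamese branches
#'
#' Sum of the multi-scale losses of the clean branch against the label and of
#' the deformed branch against the warped label.
#'
#' @param out1 `multiscale_output` of the clean patch `x`.
#' @param y label for `x`.
#' @param out2 `multiscale_output` of the deformed patch `t(x)`.
#' @param ty warped (re-binarised) label `t(y)`.
#' @param w an [mss_weights()].
#' @param p a [tversky_params()].
#' @return scalar loss.
#' @export
supervised_loss <- function(out1, y, out2, ty, w = mss_weights(),
                            p = tversky_params()) {
  mss_loss(out1, y, w, p) + mss_loss(out2, ty, w, p)
}

#' Deformation-consistency loss
#'
#' Compares the deformed branch's full-resolution prediction with the warped
#' full-resolution prediction of the clean branch:
#' `C = FTL(pred = out2, target = warp(out1, t))`. The warped target stays
#' soft (no re-binarisation) and is not gradient-stopped: gradients flow into
#' both branches, through the warp via its adjoint.
#'
#' @param out1 `multiscale_output` of the clean patch.
#' @param out2 `multiscale_output` of the deformed patch.
#' @param t the `elastic_transform` relating the branches.
#' @param p a [tversky_params()].
#' @return scalar loss.
#' @export
consistency_loss <- function(out1, out2, t, p = tversky_params()) {
  m1 <- if (inherits(out1, "multiscale_output")) out1$maps[[1]] else out1[[1]]
  m2 <- if (inherits(out2, "multiscale_output")) out2$maps[[1]] else out2[[1]]
  focal_tversky_loss(m2, warp(m1, t$field, "trilinear"), p)
}

# gradient version: returns d/d(out2 map1) and d/d(out1 map1)
consistency_grad <- function(m1, m2, t, p = tversky_params()) {
  target <- warp(m1, t$field, "trilinear")
  g <- ftl_grad(m2, target, p)
  list(loss = g$loss, dmap2 = g$dpred,
       dmap1 = warp_backward(g$dtarget, t$field))
}

#' Total training objective
#'
#' Unit-weighted sum of the supervised and consistency losses.
#'
#' @param sup supervised loss value.
#' @param cons consistency loss value.
#' @return `sup + cons`.
#' @export
total_loss <- function(sup, cons) sup + cons
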