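#' Training configuration
#'
#' Defaults follow the reference 7T MRA setting: Adam with learning rate
#' 0.01, 50 supervised epochs followed by 50 deformation-aware epochs, 8000
#' training patches drawn at random (uniformly, without replacement) each
#' epoch and a fixed set of 6000 validation patches. The tiny CPU presets
#' used in tests simply shrink the counts. Validation loss is the supervised
#' multi-scale loss in both phases so the two phases are comparable.
#'
#' @param lr Adam learning rate.
#' @param epochs_phase1 supervised warm-up epochs.
#' @param epochs_phase2 Siamese deformation-aware epochs.
#' @param batch_size patches per optimisation step.
#' @param train_patches_per_epoch patches sampled per epoch (capped at the
#'   available count; without replacement within an epoch).
#' @param val_patches maximum validation patches (fixed across epochs).
#' @param seed RNG seed governing sampling, initial transforms, etc.
#' @param checkpoint_dir directory for per-epoch checkpoints.
#' @param tversky a [tversky_params()].
#' @param weights an [mss_weights()]; length must match the network's taps.
#' @param deform_n_points candidate control-point counts for phase 2.
#' @param max_displacement elastic deformation amplitude (normalised units).
#' @param locked_border control-point rings locked to zero.
#' @param verbose emit one JSON log line per epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.01, epochs_phase1 = 50L, epochs_phase2 = 50L,
                         batch_size = 8L, train_patches_per_epoch = 8000L,
                         val_patches = 6000L, seed = 1L,
                         checkpoint_dir = tempfile("ckpt"),
                         tversky = tversky_params(),
                         weights = mss_weights(),
                         deform_n_points = c(5L, 6L, 7L),
                         max_displacement = 0.02, locked_border = 2L,
                         verbose = FALSE) {
  stopifnot(lr > 0, epochs_phase1 >= 0, epochs_phase2 >= 0, batch_size >= 1,
            train_patches_per_epoch >= 1, val_patches >= 1)
  structure(list(lr = lr, optimizer = "adam",
                 epochs_phase1 = as.integer(epochs_phase1),
                 epochs_phase2 = as.integer(epochs_phase2),
                 batch_size = as.integer(batch_size),
                 train_patches_per_epoch = as.integer(train_patches_per_epoch),
                 val_patches = as.integer(val_patches),
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 tversky = tversky, weights = weights,
                 deform_n_points = as.integer(deform_n_points),
                 max_displacement = max_displacement,
                 locked_border = as.integer(locked_border),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function(net) {
  list(m = lapply(net$params, function(p) lapply(p, function(a) a * 0)),
       v = lapply(net$params, function(p) lapply(p, function(a) a * 0)),
       t = 0L)
}

adam_step <- function(net, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(net$params)) {
    for (f in names(net$params[[nm]])) {
      g <- net$grads[[nm]][[f]]
      m <- beta1 * opt$m[[nm]][[f]] + (1 - beta1) * g
      v <- beta2 * opt$v[[nm]][[f]] + (1 - beta2) * g * g
      opt$m[[nm]][[f]] <- m
      opt$v[[nm]][[f]] <- v
      net$params[[nm]][[f]] <- net$params[[nm]][[f]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  opt
}

patch_batch5 <- function(patches, idx, field = "x") {
  p <- dim(patches[[idx[1]]][[field]])
  x <- array(0, c(p, 1L, length(idx)))
  for (i in seq_along(idx)) x[, , , 1L, i] <- patches[[idx[i]]][[field]]
  x
}

map_slice <- function(maps, n) lapply(maps, function(m) {
  array(m[, , , 1L, n], dim = dim(m)[1:3])
})

# supervised validation loss (eval mode, MSS only)
validation_loss <- function(net, val_patches, cfg) {
  total <- 0
  for (i in seq_along(val_patches)) {
    out <- ms_forward(net, val_patches[[i]]$x, train = FALSE,
                      keep_cache = FALSE)
    total <- total + mss_loss(map_slice(out$maps, 1L), val_patches[[i]]$y,
                              cfg$weights, cfg$tversky)
  }
  total / length(val_patches)
}

log_epoch <- function(cfg, phase, epoch, train_loss, val_loss) {
  if (cfg$verbose)
    message(jsonlite::toJSON(list(phase = phase, epoch = epoch,
                                  train_loss = train_loss,
                                  val_loss = val_loss, lr = cfg$lr,
                                  seed = cfg$seed), auto_unbox = TRUE))
}

history_new <- function(phase) {
  structure(list(phase = phase,
                 records = data.frame(epoch = integer(), train_loss = numeric(),
                                      val_loss = numeric(),
                                      checkpoint = character(),
                                      stringsAsFactors = FALSE)),
            class = "train_history")
}

history_add <- function(h, net, cfg, epoch, train_loss, val_loss) {
  ck <- file.path(cfg$checkpoint_dir,
                  sprintf("%s_epoch_%03d.rds", h$phase, epoch))
  save_checkpoint(net, ck)
  h$records[nrow(h$records) + 1L, ] <-
    list(epoch, train_loss, val_loss, ck)
  h
}

check_patches <- function(train_patches, val_patches) {
  if (length(train_patches) == 0L) stop("empty training patch set")
  if (length(val_patches) == 0L) stop("empty validation patch set")
}

#' Phase-1 supervised training
#'
#' Optimises the multi-scale focal Tversky loss over randomly drawn training
#' patches. Fully deterministic for a fixed `cfg$seed` (single-threaded CPU).
#'
#' @param net an `msnet`; modified in place and returned via the history.
#' @param train_patches list of `list(x = , y = )` patch pairs (3D arrays).
#' @param val_patches fixed list of validation patch pairs.
#' @param cfg a [train_config()].
#' @return a `train_history` with one record (epoch, mean train loss, val
#'   loss, checkpoint path) per epoch.
#' @export
train_supervised <- function(net, train_patches, val_patches, cfg) {
  check_patches(train_patches, val_patches)
  dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  opt <- adam_init(net)
  h <- history_new("supervised")
  n_val <- min(cfg$val_patches, length(val_patches))
  val_set <- val_patches[seq_len(n_val)]
  for (epoch in seq_len(cfg$epochs_phase1)) {
    ppe <- min(cfg$train_patches_per_epoch, length(train_patches))
    order_idx <- sample(length(train_patches), ppe)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      x5 <- patch_batch5(train_patches, bi)
      y5 <- patch_batch5(train_patches, bi, "y")
      zero_grads(net)
      out <- ms_forward(net, x5, train = TRUE)
      B <- length(bi)
      # Tversky sums pooled over the whole batch ("batch Dice" convention):
      # background-only patches then still receive a usable FP gradient.
      g <- mss_grad(out$maps, y5, cfg$weights, cfg$tversky)
      ms_backward(net, out$cache, g$dmaps)
      opt <- adam_step(net, opt, cfg$lr)
      ep_loss <- ep_loss + g$loss * B / ppe
    }
    vl <- validation_loss(net, val_set, cfg)
    h <- history_add(h, net, cfg, epoch, ep_loss, vl)
    log_epoch(cfg, "supervised", epoch, ep_loss, vl)
  }
  h
}

#' Phase-2 Siamese deformation-aware training
#'
#' Each iteration samples one fresh elastic transform per patch, forwards the
#' clean and the deformed patch through the *same* weights, and optimises
#' `supervised + consistency`: both branches' multi-scale losses plus the
#' focal Tversky disagreement between the deformed branch's prediction and
#' the warped clean-branch prediction. Gradients flow through both branches
#' and through the warp (no stop-gradient).
#'
#' @inheritParams train_supervised
#' @return a `train_history`; validation loss is the supervised multi-scale
#'   loss, comparable with phase 1.
#' @export
train_deformation_aware <- function(net, train_patches, val_patches, cfg) {
  check_patches(train_patches, val_patches)
  dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)
  opt <- adam_init(net)
  h <- history_new("deform")
  n_val <- min(cfg$val_patches, length(val_patches))
  val_set <- val_patches[seq_len(n_val)]
  for (epoch in seq_len(cfg$epochs_phase2)) {
    ppe <- min(cfg$train_patches_per_epoch, length(train_patches))
    order_idx <- sample(length(train_patches), ppe)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      B <- length(bi)
      pshape <- dim(train_patches[[bi[1]]]$x)
      transforms <- vector("list", B)
      x1 <- patch_batch5(train_patches, bi)
      x2 <- array(0, c(pshape, 1L, B))
      ty <- vector("list", B)
      for (n in seq_len(B)) {
        transforms[[n]] <- sample_elastic_transform(
          pshape, cfg$deform_n_points, cfg$max_displacement,
          cfg$locked_border)
        pair <- apply_transform_pair(transforms[[n]],
                                     train_patches[[bi[n]]]$x,
                                     train_patches[[bi[n]]]$y)
        x2[, , , 1L, n] <- pair$x
        ty[[n]] <- pair$y
      }
      zero_grads(net)
      out1 <- ms_forward(net, x1, train = TRUE)
      out2 <- ms_forward(net, x2, train = TRUE)
      y1 <- patch_batch5(train_patches, bi, "y")
      y2 <- y1
      for (n in seq_len(B)) y2[, , , 1L, n] <- ty[[n]]
      # supervised terms, Tversky sums pooled over the batch
      g1 <- mss_grad(out1$maps, y1, cfg$weights, cfg$tversky)
      g2 <- mss_grad(out2$maps, y2, cfg$weights, cfg$tversky)
      # consistency: warp the clean branch per sample, pool the comparison
      target5 <- array(0, dim(out1$maps[[1]]))
      for (n in seq_len(B))
        target5[, , , 1L, n] <- warp(
          array(out1$maps[[1]][, , , 1L, n], pshape),
          transforms[[n]]$field, "trilinear")
      gc_ <- ftl_grad(out2$maps[[1]], target5, cfg$tversky)
      dmaps1 <- g1$dmaps
      dmaps2 <- g2$dmaps
      dmaps2[[1]] <- dmaps2[[1]] + gc_$dpred
      for (n in seq_len(B))
        dmaps1[[1]][, , , 1L, n] <- dmaps1[[1]][, , , 1L, n] +
          warp_backward(array(gc_$dtarget[, , , 1L, n], pshape),
                        transforms[[n]]$field)
      ms_backward(net, out1$cache, dmaps1)
      ms_backward(net, out2$cache, dmaps2)
      opt <- adam_step(net, opt, cfg$lr)
      ep_loss <- ep_loss + (g1$loss + g2$loss + gc_$loss) * B / ppe
    }
    vl <- validation_loss(net, val_set, cfg)
    h <- history_add(h, net, cfg, epoch, ep_loss, vl)
    log_epoch(cfg, "deform", epoch, ep_loss, vl)
  }
  h
}

#' Select the checkpoint with the lowest validation loss
#'
#' Ties resolve to the earliest epoch.
#'
#' @param h a `train_history` (or a list of them, searched jointly).
#' @return the checkpoint path, with attribute `epoch`.
#' @export
select_best_checkpoint <- function(h) {
  rec <- if (inherits(h, "train_history")) h$records
         else do.call(rbind, lapply(h, function(x) x$records))
  if (nrow(rec) == 0L) stop("empty training history")
  i <- which.min(rec$val_loss)
  structure(rec$checkpoint[i], epoch = rec$epoch[i])
}
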