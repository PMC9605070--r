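#' Network configuration for the multi-scale-supervised 3D U-Net
#'
#' The backbone is an encoder-decoder with `depth = 4` max-pool
#' downsamplings, two (conv 3x3x3 -> batch norm -> ReLU) blocks per level,
#' channel width doubling from `base_channels`, trilinear 2x upsampling with
#' skip concatenation in the decoder, and 1x1x1 sigmoid heads at the last
#' `supervision_taps` decoder levels. The deeper heads are resampled to label
#' resolution with nearest-neighbour interpolation. `base_channels = 64` is
#' the classic U-Net width; the tiny preset (8) is meant for CPU-scale runs.
#' With `supervision_taps = 1` the architecture degrades to a plain U-Net.
#'
#' @param in_channels input channels (1 for magnitude MRA).
#' @param base_channels channels of the first encoder level, >= 2.
#' @param depth number of poolings; the faithful preset is 4.
#' @param supervision_taps number of supervision heads (1 to 3).
#' @param upsample_mode decoder upsampling; `"trilinear"`.
#' @param norm normalisation; `"batch"`.
#' @param activation `"relu"`.
#' @param final_activation `"sigmoid"`.
#' @return a `network_config` list.
#' @export
network_config <- function(in_channels = 1L, base_channels = 64L, depth = 4L,
                           supervision_taps = 3L,
                           upsample_mode = "trilinear", norm = "batch",
                           activation = "relu",
                           final_activation = "sigmoid") {
  bad <- character()
  if (in_channels < 1) bad <- c(bad, "in_channels")
  if (base_channels < 2) bad <- c(bad, "base_channels")
  if (depth != 4) bad <- c(bad, "depth")
  if (!supervision_taps %in% 1:3) bad <- c(bad, "supervision_taps")
  if (upsample_mode != "trilinear") bad <- c(bad, "upsample_mode")
  if (norm != "batch") bad <- c(bad, "norm")
  if (activation != "relu") bad <- c(bad, "activation")
  if (final_activation != "sigmoid") bad <- c(bad, "final_activation")
  if (length(bad))
    stop("invalid network config field(s): ", paste(bad, collapse = ", "))
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 supervision_taps = as.integer(supervision_taps),
                 upsample_mode = upsample_mode, norm = norm,
                 activation = activation,
                 final_activation = final_activation),
            class = "network_config")
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# (input channels, output channels) of every conv block, given base width b
net_block_channels <- function(cfg) {
  b <- cfg$base_channels
  list(
    enc1a = c(cfg$in_channels, b), enc1b = c(b, b),
    enc2a = c(b, 2 * b),           enc2b = c(2 * b, 2 * b),
    enc3a = c(2 * b, 4 * b),       enc3b = c(4 * b, 4 * b),
    enc4a = c(4 * b, 8 * b),       enc4b = c(8 * b, 8 * b),
    botta = c(8 * b, 16 * b),      bottb = c(16 * b, 16 * b),
    dec4a = c(24 * b, 8 * b),      dec4b = c(8 * b, 8 * b),
    dec3a = c(12 * b, 4 * b),      dec3b = c(4 * b, 4 * b),
    dec2a = c(6 * b, 2 * b),       dec2b = c(2 * b, 2 * b),
    dec1a = c(3 * b, b),           dec1b = c(b, b))
}

net_head_channels <- function(cfg) {
  b <- cfg$base_channels
  list(head1 = b, head2 = 2 * b, head3 = 4 * b)[seq_len(cfg$supervision_taps)]
}

#' Build a multi-scale-supervised U-Net
#'
#' Weights use He-normal initialisation drawn from R's RNG seeded with
#' `seed`, so the same seed yields bit-identical networks.
#'
#' @param cfg a [network_config()].
#' @param seed integer RNG seed for the initialisation.
#' @return a network handle (environment of class `msnet`).
#' @export
build_network <- function(cfg = network_config(), seed = 42L) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$seed <- as.integer(seed)
  params <- list()
  state <- list()
  for (nm in names(net_block_channels(cfg))) {
    ch <- net_block_channels(cfg)[[nm]]
    sd <- sqrt(2 / (27 * ch[1]))
    params[[nm]] <- list(
      w = array(rnorm(27 * ch[1] * ch[2], sd = sd),
                dim = c(3, 3, 3, ch[1], ch[2])),
      b = numeric(ch[2]),
      gamma = rep(1, ch[2]), beta = numeric(ch[2]))
    state[[nm]] <- list(rmean = numeric(ch[2]), rvar = rep(1, ch[2]))
  }
  for (nm in names(net_head_channels(cfg))) {
    cin <- net_head_channels(cfg)[[nm]]
    params[[nm]] <- list(
      w = matrix(rnorm(cin, sd = sqrt(2 / cin)), cin, 1),
      b = 0)
  }
  net$params <- params
  net$state <- state
  class(net) <- "msnet"
  net
}

#' @export
print.msnet <- function(x, ...) {
  cat(sprintf("<msnet> base %d, %d taps, %s trainable parameters\n",
              x$cfg$base_channels, x$cfg$supervision_taps,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param net an `msnet`.
#' @return integer count.
#' @export
n_params <- function(net) {
  sum(vapply(net$params, function(p) sum(vapply(p, length, 0L)), 0))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

as_batch5 <- function(x, in_channels = 1L) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, in_channels, 1L)
  } else if (length(d) != 5L) {
    stop("expected a 3D patch or a (W,H,D,C,N) batch")
  }
  x
}

conv_block_fwd <- function(net, nm, x, train, cache) {
  p <- net$params[[nm]]
  cv <- cpp_conv3_fwd(x, dim(x), p$w, p$b)
  st <- net$state[[nm]]
  bn <- cpp_bn_fwd(cv, dim(cv), p$gamma, p$beta, train, st$rmean, st$rvar,
                   BN_EPS)
  if (train) {
    net$state[[nm]]$rmean <- (1 - BN_MOMENTUM) * st$rmean + BN_MOMENTUM * bn$mean
    net$state[[nm]]$rvar <- (1 - BN_MOMENTUM) * st$rvar + BN_MOMENTUM * bn$var
  }
  y <- bn$y
  y[y < 0] <- 0
  if (!is.null(cache))
    cache[[nm]] <- list(x = x, cv = cv, mean = bn$mean, invstd = bn$invstd,
                        mask = bn$y > 0)
  y
}

conv_block_bwd <- function(net, nm, dy, cache) {
  cc <- cache[[nm]]
  p <- net$params[[nm]]
  dy <- dy * cc$mask
  bnb <- cpp_bn_bwd(cc$cv, dim(cc$cv), dy, p$gamma, cc$mean, cc$invstd)
  cvb <- cpp_conv3_bwd(cc$x, dim(cc$x), p$w, bnb$dx, length(p$b))
  g <- net$grads[[nm]]
  g$w <- g$w + cvb$dw; g$b <- g$b + cvb$db
  g$gamma <- g$gamma + bnb$dgamma; g$beta <- g$beta + bnb$dbeta
  net$grads[[nm]] <- g
  cvb$dx
}

head_fwd <- function(net, nm, x, cache) {
  p <- net$params[[nm]]
  z <- cpp_conv1_fwd(x, dim(x), p$w, p$b)
  s <- sigmoid(z)
  if (!is.null(cache)) cache[[nm]] <- list(x = x, s = s)
  s
}

head_bwd <- function(net, nm, ds, cache) {
  cc <- cache[[nm]]
  p <- net$params[[nm]]
  dz <- ds * cc$s * (1 - cc$s)
  cb <- cpp_conv1_bwd(cc$x, dim(cc$x), p$w, dz, 1L)
  g <- net$grads[[nm]]
  g$w <- g$w + cb$dw; g$b <- g$b + cb$db
  net$grads[[nm]] <- g
  cb$dx
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

# Full forward pass. Returns list(maps = <taps>, cache = env | NULL).
# maps are (W,H,D,1,N) probability arrays, all at full resolution.
ms_forward <- function(net, x, train = FALSE, keep_cache = train) {
  x <- as_batch5(x, net$cfg$in_channels)
  sp <- dim(x)[1:3]
  if (any(sp %% 16L != 0L))
    stop("spatial dimensions (", paste(sp, collapse = ","),
         ") must be divisible by 16")
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  e1 <- conv_block_fwd(net, "enc1b",
                       conv_block_fwd(net, "enc1a", x, train, cache),
                       train, cache)
  p1 <- cpp_maxpool2_fwd(e1, dim(e1))
  e2 <- conv_block_fwd(net, "enc2b",
                       conv_block_fwd(net, "enc2a", p1$y, train, cache),
                       train, cache)
  p2 <- cpp_maxpool2_fwd(e2, dim(e2))
  e3 <- conv_block_fwd(net, "enc3b",
                       conv_block_fwd(net, "enc3a", p2$y, train, cache),
                       train, cache)
  p3 <- cpp_maxpool2_fwd(e3, dim(e3))
  e4 <- conv_block_fwd(net, "enc4b",
                       conv_block_fwd(net, "enc4a", p3$y, train, cache),
                       train, cache)
  p4 <- cpp_maxpool2_fwd(e4, dim(e4))
  bt <- conv_block_fwd(net, "bottb",
                       conv_block_fwd(net, "botta", p4$y, train, cache),
                       train, cache)
  u4 <- cpp_uptri2_fwd(bt, dim(bt))
  d4 <- conv_block_fwd(net, "dec4b",
                       conv_block_fwd(net, "dec4a", concat_ch(u4, e4),
                                      train, cache), train, cache)
  u3 <- cpp_uptri2_fwd(d4, dim(d4))
  d3 <- conv_block_fwd(net, "dec3b",
                       conv_block_fwd(net, "dec3a", concat_ch(u3, e3),
                                      train, cache), train, cache)
  u2 <- cpp_uptri2_fwd(d3, dim(d3))
  d2 <- conv_block_fwd(net, "dec2b",
                       conv_block_fwd(net, "dec2a", concat_ch(u2, e2),
                                      train, cache), train, cache)
  u1 <- cpp_uptri2_fwd(d2, dim(d2))
  d1 <- conv_block_fwd(net, "dec1b",
                       conv_block_fwd(net, "dec1a", concat_ch(u1, e1),
                                      train, cache), train, cache)
  taps <- net$cfg$supervision_taps
  maps <- list(head_fwd(net, "head1", d1, cache))
  if (taps >= 2) {
    h2 <- head_fwd(net, "head2", d2, cache)
    maps[[2]] <- cpp_upnn_fwd(h2, dim(h2), 2L)
  }
  if (taps >= 3) {
    h3 <- head_fwd(net, "head3", d3, cache)
    maps[[3]] <- cpp_upnn_fwd(h3, dim(h3), 4L)
  }
  if (keep_cache) {
    cache$pool <- list(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
    cache$dims <- list(e1 = dim(e1), e2 = dim(e2), e3 = dim(e3),
                       e4 = dim(e4), bt = dim(bt), d4 = dim(d4),
                       d3 = dim(d3), d2 = dim(d2), d1 = dim(d1),
                       x = dim(x))
  }
  list(maps = maps, cache = cache)
}

# Backward pass: dmaps is a list of gradients w.r.t. the full-resolution
# probability maps (same length/order as ms_forward()$maps). Accumulates
# parameter gradients into net$grads.
ms_backward <- function(net, cache, dmaps) {
  taps <- net$cfg$supervision_taps
  dims <- cache$dims
  dd1 <- head_bwd(net, "head1", dmaps[[1]], cache)
  dd2 <- array(0, dims$d2)
  dd3 <- array(0, dims$d3)
  if (taps >= 2) {
    dh2 <- cpp_upnn_bwd(dmaps[[2]], dim(dmaps[[2]]), 2L)
    dd2 <- dd2 + head_bwd(net, "head2", dh2, cache)
  }
  if (taps >= 3) {
    dh3 <- cpp_upnn_bwd(dmaps[[3]], dim(dmaps[[3]]), 4L)
    dd3 <- dd3 + head_bwd(net, "head3", dh3, cache)
  }
  split_ch <- function(d, n_up) {
    list(up = d[, , , seq_len(n_up), , drop = FALSE],
         skip = d[, , , -seq_len(n_up), , drop = FALSE])
  }
  # dec1
  din <- conv_block_bwd(net, "dec1a",
                        conv_block_bwd(net, "dec1b", dd1, cache), cache)
  s <- split_ch(din, dims$d2[4])
  dd2 <- dd2 + cpp_uptri2_bwd(s$up, dim(s$up))
  de1 <- s$skip
  # dec2
  din <- conv_block_bwd(net, "dec2a",
                        conv_block_bwd(net, "dec2b", dd2, cache), cache)
  s <- split_ch(din, dims$d3[4])
  dd3 <- dd3 + cpp_uptri2_bwd(s$up, dim(s$up))
  de2 <- s$skip
  # dec3
  din <- conv_block_bwd(net, "dec3a",
                        conv_block_bwd(net, "dec3b", dd3, cache), cache)
  s <- split_ch(din, dims$d4[4])
  dd4 <- cpp_uptri2_bwd(s$up, dim(s$up))
  de3 <- s$skip
  # dec4
  din <- conv_block_bwd(net, "dec4a",
                        conv_block_bwd(net, "dec4b", dd4, cache), cache)
  s <- split_ch(din, dims$bt[4])
  dbt <- cpp_uptri2_bwd(s$up, dim(s$up))
  de4 <- s$skip
  # bottleneck and encoder (skip grads join after the pools)
  dp4 <- conv_block_bwd(net, "botta",
                        conv_block_bwd(net, "bottb", dbt, cache), cache)
  de4 <- de4 + cpp_maxpool2_bwd(dp4, cache$pool$p4$idx, dims$e4)
  dp3 <- conv_block_bwd(net, "enc4a",
                        conv_block_bwd(net, "enc4b", de4, cache), cache)
  de3 <- de3 + cpp_maxpool2_bwd(dp3, cache$pool$p3$idx, dims$e3)
  dp2 <- conv_block_bwd(net, "enc3a",
                        conv_block_bwd(net, "enc3b", de3, cache), cache)
  de2 <- de2 + cpp_maxpool2_bwd(dp2, cache$pool$p2$idx, dims$e2)
  dp1 <- conv_block_bwd(net, "enc2a",
                        conv_block_bwd(net, "enc2b", de2, cache), cache)
  de1 <- de1 + cpp_maxpool2_bwd(dp1, cache$pool$p1$idx, dims$e1)
  conv_block_bwd(net, "enc1a",
                 conv_block_bwd(net, "enc1b", de1, cache), cache)
  invisible(NULL)
}

zero_grads <- function(net) {
  net$grads <- lapply(net$params, function(p) lapply(p, function(a) a * 0))
  invisible(net)
}

#' Forward a patch through the network
#'
#' @param net an `msnet` from [build_network()].
#' @param patch 3D array (spatial dims divisible by 16) or a `(W,H,D,C,N)`
#'   batch.
#' @param train use batch statistics and keep the autodiff cache (internal
#'   training mode); default `FALSE` = deterministic evaluation mode.
#' @return a `multiscale_output`: list whose `maps` element holds one
#'   full-resolution probability array per supervision tap (values strictly
#'   inside (0,1)), index 1 = output head. For a 3D input the maps are 3D.
#' @export
forward <- function(net, patch, train = FALSE) {
  was3d <- length(dim(patch)) == 3L
  out <- ms_forward(net, patch, train = train, keep_cache = FALSE)
  maps <- out$maps
  if (was3d) maps <- lapply(maps, function(m) array(m, dim = dim(m)[1:3]))
  structure(list(maps = maps), class = "multiscale_output")
}

#' Save / load network checkpoints
#'
#' The checkpoint stores weights, running statistics, the
#' [network_config()] and the init seed; a JSON sidecar (`<path>.json`)
#' records the config for provenance.
#'
#' @param net an `msnet`.
#' @param path checkpoint file path.
#' @return `save_checkpoint()` returns `path`; `load_checkpoint()` the
#'   restored `msnet`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = unclass(net$cfg), seed = net$seed, params = net$params,
               state = net$state), path)
  jsonlite::write_json(list(config = unclass(net$cfg), seed = net$seed),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- new.env(parent = emptyenv())
  net$cfg <- do.call(network_config, obj$cfg)
  net$seed <- obj$seed
  net$params <- obj$params
  net$state <- obj$state
  class(net) <- "msnet"
  net
}
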