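tiny_train_setup <- function(n = 12L, seed = 50L) {
  patches <- phantom_patches(tiny_phantom_spec(seed = seed))
  # keep a mix of vessel and background patches
  patches[seq_len(min(n, length(patches)))]
}

test_that("supervised training keeps books and is seed-deterministic", {
  tr <- tiny_train_setup()
  cfg <- train_config(epochs_phase1 = 2, epochs_phase2 = 0, batch_size = 4,
                      train_patches_per_epoch = 8, val_patches = 4,
                      seed = 123)
  net <- tiny_net(base = 2, seed = 1)
  h <- train_supervised(net, tr, tr[1:4], cfg)
  expect_s3_class(h, "train_history")
  expect_equal(nrow(h$records), 2)
  expect_true(all(is.finite(h$records$train_loss)))
  expect_true(all(is.finite(h$records$val_loss)))
  expect_true(all(file.exists(h$records$checkpoint)))
  # identical seed, identical curves
  net2 <- tiny_net(base = 2, seed = 1)
  cfg2 <- train_config(epochs_phase1 = 2, epochs_phase2 = 0, batch_size = 4,
                       train_patches_per_epoch = 8, val_patches = 4,
                       seed = 123)
  h2 <- train_supervised(net2, tr, tr[1:4], cfg2)
  expect_equal(h$records$train_loss, h2$records$train_loss)
  expect_equal(h$records$val_loss, h2$records$val_loss)
  expect_error(train_supervised(net, list(), tr[1:4], cfg), "empty")
  expect_error(train_supervised(net, tr, list(), cfg), "empty")
})

test_that("a single-patch overfit strictly reduces the training loss", {
  tr <- tiny_train_setup()
  vessel <- tr[[which.max(vapply(tr, function(p) sum(p$y), 0))]]
  cfg <- train_config(epochs_phase1 = 50, epochs_phase2 = 0, batch_size = 1,
                      train_patches_per_epoch = 1, val_patches = 1,
                      seed = 9)
  net <- tiny_net(base = 2, seed = 2)
  h <- train_supervised(net, list(vessel), list(vessel), cfg)
  expect_lt(h$records$train_loss[50], h$records$train_loss[1])
})

test_that("deformation-aware training optimises the Siamese objective", {
  tr <- tiny_train_setup()
  vessel <- tr[[which.max(vapply(tr, function(p) sum(p$y), 0))]]
  cfg <- train_config(epochs_phase1 = 0, epochs_phase2 = 50, batch_size = 1,
                      train_patches_per_epoch = 1, val_patches = 1, seed = 4)
  net <- tiny_net(base = 2, seed = 5)
  h <- train_deformation_aware(net, list(vessel), list(vessel), cfg)
  expect_equal(nrow(h$records), 50)
  expect_true(all(is.finite(h$records$train_loss)))
  # the overfit run reduces the total (supervised + consistency) loss
  expect_lt(h$records$train_loss[50], h$records$train_loss[1])
})

test_that("zero-amplitude deformation degenerates to twice the MSS loss", {
  tr <- tiny_train_setup()
  vessel <- tr[[which.max(vapply(tr, function(p) sum(p$y), 0))]]
  net <- tiny_net(base = 2, seed = 6)
  # evaluation-mode network: identical branches, binary-free consistency
  out <- forward(net, vessel$x)
  t0 <- sample_elastic_transform(dim(vessel$x), 5, max_displacement = 0)
  sup <- supervised_loss(out, vessel$y, out, vessel$y)
  expect_equal(sup, 2 * mss_loss(out, vessel$y), tolerance = 1e-12)
  # consistency of identical binarised maps under the identity transform is 0
  bin <- lapply(out$maps, function(m) (m >= 0.5) * 1)
  expect_equal(consistency_loss(bin, bin, t0), 0)
  expect_equal(total_loss(sup, 0), sup)
})

test_that("short two-phase runs stay finite on phantoms", {
  tr <- tiny_train_setup(n = 16)
  cfg <- train_config(epochs_phase1 = 2, epochs_phase2 = 2, batch_size = 4,
                      train_patches_per_epoch = 8, val_patches = 4, seed = 77)
  for (seed in 1:2) {
    net <- tiny_net(base = 2, seed = seed)
    h1 <- train_supervised(net, tr, tr[1:4], cfg)
    h2 <- train_deformation_aware(net, tr, tr[1:4], cfg)
    expect_true(all(is.finite(c(h1$records$val_loss, h2$records$val_loss))))
  }
})

test_that("checkpoint selection minimises validation loss with early ties", {
  h <- deformseg:::history_new("supervised")
  h$records <- data.frame(epoch = 1:3, train_loss = c(1, 1, 1),
                          val_loss = c(0.5, 0.3, 0.4),
                          checkpoint = c("a", "b", "c"),
                          stringsAsFactors = FALSE)
  expect_equal(as.character(select_best_checkpoint(h)), "b")
  expect_equal(attr(select_best_checkpoint(h), "epoch"), 2)
  h$records$val_loss <- c(0.3, 0.3, 0.4)
  expect_equal(as.character(select_best_checkpoint(h)), "a")
  h$records$val_loss <- c(0.5, 0.4, 0.3)
  expect_equal(as.character(select_best_checkpoint(h)), "c")
  h$records <- h$records[0, ]
  expect_error(select_best_checkpoint(h), "empty")
})
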