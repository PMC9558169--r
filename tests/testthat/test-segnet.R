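# A miniature configuration keeps these unit tests fast; the full-size
# training run is exercised in the acceptance suite.
tiny_cfg <- function(seed = 1L)
  seg_model_config(enc_channels = c(4L, 6L), aspp_channels = 4L,
                   dec_channels = 4L, patch_px = 32L, epochs = 10L,
                   batch_size = 4L, batches_per_epoch = 30L, seed = seed)

tiny_data <- function(n = 4L, nr = 64L, nc = 64L, seed = 5) {
  set.seed(seed)
  frames <- list(); masks <- list()
  for (i in seq_len(n)) {
    m <- matrix(0L, nr, nc)
    r0 <- sample(10:(nr - 20), 1)
    m[r0:(r0 + 4), 5:(nc - 5)] <- 1L
    img <- array(0.2 + rnorm(nr * nc * 3, 0, 0.03), c(nr, nc, 3))
    for (ch in 1:3) img[, , ch][m == 1L] <- 0.9
    frames[[i]] <- pmin(pmax(img, 0), 1); masks[[i]] <- m
  }
  list(frames = frames, masks = masks)
}

test_that("model configuration enforces its structural invariants", {
  expect_error(seg_model_config(aspp_rates = c(1, 2)), "distinct positive")
  expect_error(seg_model_config(aspp_rates = c(1, 2, 2)), "distinct")
  expect_error(seg_model_config(patch_px = 50L), "divisible")
  cfg <- seg_model_config()
  expect_equal(2L^length(cfg$enc_channels), 4L)   # decoder upsamples x4 total
})

test_that("sub-pixel shuffle is an exact bijection", {
  a <- array(seq_len(8 * 8 * 12), c(8, 8, 12))
  s <- rhizotrack:::pixel_shuffle(a, 2L)
  expect_equal(dim(s), c(16L, 16L, 3L))
  expect_identical(rhizotrack:::pixel_unshuffle(s, 2L), a)
})

test_that("training reduces the loss, is seeded, and learns a separable scene", {
  td <- tiny_data()
  model <- train_seg_model(td$frames, td$masks, tiny_cfg(seed = 3))
  expect_true(all(is.finite(model$epoch_loss)))
  expect_lt(tail(model$epoch_loss, 1), model$epoch_loss[1])

  # determinism: identical seeds give identical losses, different seeds differ
  model2 <- train_seg_model(td$frames, td$masks, tiny_cfg(seed = 3))
  expect_identical(model$epoch_loss, model2$epoch_loss)
  model3 <- train_seg_model(td$frames, td$masks, tiny_cfg(seed = 4))
  expect_false(identical(model$epoch_loss, model3$epoch_loss))

  # prediction on a training frame recovers most of the bright ribbon
  pm <- predict_mask(model, td$frames[[1]])
  expect_equal(mask_provenance(pm), "model")
  expect_equal(dim(pm), dim(td$masks[[1]]))
  expect_gt(evaluate_masks(pm, td$masks[[1]])$iou, 0.5)

  # prediction is deterministic
  expect_identical(pm, predict_mask(model, td$frames[[1]]))

  # mask density is non-increasing in the threshold
  d <- vapply(c(0.1, 0.5, 0.9),
              function(th) mean(predict_mask(model, td$frames[[1]], th)),
              numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("degenerate inputs are rejected or learned as background", {
  td <- tiny_data()
  expect_error(train_seg_model(list(), list(), tiny_cfg()), "empty training")
  bad <- td$masks; bad[[1]] <- bad[[1]][1:10, 1:10]
  expect_error(train_seg_model(td$frames, bad, tiny_cfg()), "mismatch")
  expect_error(predict_mask(rhizotrack:::init_seg_model(tiny_cfg()),
                            td$frames[[1]]), "not trained")

  # all-background labels: model predicts almost no foreground
  zero <- lapply(td$masks, function(m) m * 0L)
  m0 <- train_seg_model(td$frames, zero, tiny_cfg(seed = 6))
  expect_lt(mean(predict_mask(m0, td$frames[[2]])), 0.01)
})

test_that("checkpoints round-trip through a single file", {
  td <- tiny_data(n = 2L)
  model <- train_seg_model(td$frames, td$masks, tiny_cfg(seed = 9))
  path <- withr::local_tempfile(fileext = ".rds")
  save_seg_model(model, path)
  back <- load_seg_model(path)
  expect_identical(predict_mask(back, td$frames[[1]]),
                   predict_mask(model, td$frames[[1]]))
})
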