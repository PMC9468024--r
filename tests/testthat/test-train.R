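test_that("the learning-rate schedule follows alpha * 0.7^floor(k/4) exactly", {
  expect_identical(lr_schedule(8), 0.001 * 0.7^2)
  k <- 0:40
  expect_identical(lr_schedule(k), 0.001 * 0.7^(k %/% 4))
  expect_identical(lr_schedule(3), 0.001)
  expect_identical(lr_schedule(4), 0.0007)
  expect_error(lr_schedule(1, alpha = 0), "alpha")
  expect_error(lr_schedule(1, drop_factor = 1.1), "drop_factor")
})

test_that("training config validates its invariants", {
  expect_error(train_config(momentum = 1), "momentum")
  expect_error(train_config(val_split = 0), "val_split")
  expect_error(train_config(drop_every = 0), "cadences")
  cfg <- train_config()
  expect_equal(cfg$alpha, 0.001)
  expect_equal(cfg$drop_factor, 0.7)
  expect_equal(cfg$l2, 0.005)
  expect_equal(cfg$momentum, 0.9)
})

seg_dataset <- function(n = 2, seed0 = 31) {
  lapply(seq_len(n), function(i) {
    ig <- cached_render(5, seed0 + i)
    list(image = ig$image, mask = ig$tile_mask)
  })
}

test_that("segmenter training traces validation at the configured cadence", {
  ds <- seg_dataset()
  cfg <- train_config(epochs = 8, val_every = 4, seed = 5)
  model <- train_segmenter(ds, cfg, pixels_per_image = 1500)
  expect_s3_class(model, "seg_model")
  expect_equal(model$trace$epoch, c(4, 8))
  expect_equal(model$trace$lr, lr_schedule(c(4, 8)))
  expect_true(all(is.finite(model$trace$val_accuracy)))
  # deterministic per seed
  model2 <- train_segmenter(ds, cfg, pixels_per_image = 1500)
  expect_identical(model$trace, model2$trace)
  expect_identical(model$W, model2$W)
  expect_error(train_segmenter(list()), "at least 2")
})

test_that("a trained segmenter fits its own training images (overfit check)", {
  ds <- seg_dataset()
  model <- train_segmenter(ds, train_config(epochs = 24, seed = 5),
                           pixels_per_image = 3000)
  acc <- pixel_accuracy(segment_tiles(ds[[1]]$image, model = model),
                        ds[[1]]$mask)
  expect_gte(acc, 0.95)
})

test_that("models serialise to a single versioned file", {
  ds <- seg_dataset()
  model <- train_segmenter(ds, train_config(epochs = 4, seed = 5),
                           pixels_per_image = 500)
  path <- tempfile(fileext = ".model")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(back$W, model$W)
  saveRDS(list(x = 1), path)
  expect_error(read_model(path), "not an icescreen model")
})
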