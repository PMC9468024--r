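test_that("classical segmentation reaches 0.99 pixel accuracy on noiseless scenes", {
  for (mg in c(5, 10)) {
    ig <- render_interferogram(build_scene(magnification = mg, seed = 9),
                               noise_sd = 0, seed = 1)
    acc <- pixel_accuracy(segment_tiles(ig), ig$tile_mask)
    expect_gte(acc, 0.99)
  }
})

test_that("a bar-free image yields an empty tile mask", {
  flat <- array(0.08, c(128, 128, 3))
  expect_warning(m <- segment_tiles(flat), "no grid bars")
  expect_equal(sum(m), 0)
})

test_that("post-processing fills holes and removes asymmetric components", {
  m <- matrix(0, 60, 60)
  m[10:30, 10:30] <- 1
  m[18:22, 18:22] <- 0 # interior hole
  det <- postprocess_mask(m, min_area = 10)
  expect_length(det, 1)
  expect_equal(det[[1]]$area, 21 * 21) # hole filled
  # 3:1 elongated interior component removed at max_aspect 1.5
  m2 <- matrix(0, 60, 60)
  m2[10:15, 10:27] <- 1
  m2[30:45, 30:45] <- 1
  det2 <- postprocess_mask(m2, max_aspect = 1.5, min_area = 10)
  expect_length(det2, 1)
  expect_equal(unname(det2[[1]]$bbox["row0"]), 29)
})

test_that("diagonal-adjacent squares stay separate (4-connectivity)", {
  m <- matrix(0, 40, 40)
  m[5:15, 5:15] <- 1
  m[16:26, 16:26] <- 1 # shares only the corner
  det <- postprocess_mask(m, min_area = 10)
  expect_length(det, 2)
  # row-major ordering by bbox origin
  expect_equal(unname(vapply(det, function(d) d$bbox[["row0"]], 0)), c(4, 15))
  expect_equal(unname(vapply(det, function(d) d$id, 0L)), c(1L, 2L))
})

test_that("border-touching partial squares are kept and flagged", {
  m <- matrix(0, 50, 50)
  m[1:10, 20:45] <- 1 # elongated but touching the border
  m[25:45, 20:40] <- 1
  det <- postprocess_mask(m, min_area = 30)
  expect_length(det, 2)
  flags <- vapply(det, function(d) d$touches_border, TRUE)
  expect_equal(sum(flags), 1)
})

test_that("pixel accuracy counts agreements", {
  m <- matrix(rep(c(0, 1), 50), 10, 10)
  expect_equal(pixel_accuracy(m, m), 1)
  expect_equal(pixel_accuracy(m, 1 - m), 0)
  m2 <- m; m2[1:10] <- 1 - m2[1:10]
  expect_equal(pixel_accuracy(m2, m), 0.9)
  expect_error(pixel_accuracy(m, matrix(0, 5, 5)), "shape")
})

test_that("augmentation yields two rotations and two crops, deterministically", {
  ig <- cached_render(5, 21)
  aug <- augment(ig$image, ig$tile_mask, seed = 4)
  expect_length(aug, 4)
  expect_equal(vapply(aug, `[[`, "", "kind"),
               c("rotation", "rotation", "crop", "crop"))
  for (a in aug) {
    expect_true(all(a$mask %in% c(0, 1)))
    expect_identical(dim(a$image)[1:2], dim(a$mask))
  }
  # identity rotation returns the input pair unchanged
  aug0 <- augment(ig$image, ig$tile_mask, seed = 4, rot_angles = c(0, 0))
  expect_identical(aug0[[1]]$image, ig$image)
  expect_identical(aug0[[1]]$mask, ig$tile_mask)
  # rotation approximately preserves the mask foreground fraction
  frac <- mean(ig$tile_mask)
  rot <- aug[[1]]
  valid <- icescreen:::from_ebimage(
    EBImage::rotate(icescreen:::as_ebimage(matrix(1, nrow(ig$tile_mask),
                                                  ncol(ig$tile_mask))),
                    rot$angle, filter = "none", bg.col = 0))
  frac_rot <- sum(rot$mask) / max(sum(valid), 1)
  expect_lt(abs(frac_rot - frac), 0.1)
  # determinism
  aug2 <- augment(ig$image, ig$tile_mask, seed = 4)
  expect_identical(aug, aug2)
})
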