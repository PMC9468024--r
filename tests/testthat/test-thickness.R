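test_that("thickness map handles equal intensities, 1/e and the 1.2 ratio", {
  mk_pair <- function(unf, fil, lambda = 322) {
    structure(list(unfiltered = unf, filtered = fil, lambda_inel = lambda,
                   pixel_size_nm = 20), class = "em_pair")
  }
  tm0 <- thickness_map(mk_pair(matrix(800, 3, 3), matrix(800, 3, 3)))
  expect_equal(tm0$thickness, matrix(0, 3, 3))
  tm1 <- thickness_map(mk_pair(matrix(exp(1), 2, 2), matrix(1, 2, 2)))
  expect_equal(tm1$thickness, matrix(322, 2, 2), tolerance = 1e-12)
  tm2 <- thickness_map(mk_pair(matrix(1200, 1, 1), matrix(1000, 1, 1)))
  expect_equal(tm2$thickness[1, 1], 322 * log(1.2), tolerance = 1e-12)
  expect_equal(tm2$thickness[1, 1], 58.7, tolerance = 1e-3)
  expect_error(thickness_map(mk_pair(matrix(1, 2, 2), matrix(1, 3, 3))),
               "shape")
})

test_that("invalid and negative-ratio pixels are flagged", {
  unf <- matrix(c(0, 900, 1000, 1000), 2)
  fil <- matrix(c(100, 1000, 500, -2), 2)
  pair <- structure(list(unfiltered = unf, filtered = fil, lambda_inel = 322,
                         pixel_size_nm = 20), class = "em_pair")
  tm <- thickness_map(pair)
  expect_false(tm$valid[1, 1]) # zero unfiltered intensity
  expect_false(tm$valid[2, 2]) # negative filtered intensity
  expect_true(tm$clipped[2, 1]) # apparent negative thickness clipped to 0
  expect_equal(tm$thickness[2, 1], 0)
})

test_that("hole detection recovers the 7x7 lattice and excludes border holes", {
  f <- sample_thickness_field(2, seed = 3, n_px = 210)
  pr <- simulate_em_square(f, square_um = 21, noise_sd = 0)
  truth <- attr(pr, "holes")
  det <- detect_holes(pr$filtered, hole_radius_px = truth$radius[1])
  expect_equal(nrow(det), 49)
  # centres match the generator geometry to within a pixel
  for (j in seq_len(nrow(truth))) {
    d <- sqrt((det$row - truth$row[j])^2 + (det$col - truth$col[j])^2)
    expect_lt(min(d), 1.5)
  }
  # cropping the frame makes the outer ring incomplete: detections drop
  crop <- pr$filtered[8:203, 8:203]
  det_crop <- detect_holes(crop, hole_radius_px = truth$radius[1])
  expect_lt(nrow(det_crop), 49)
  expect_true(all(det_crop$row > truth$radius[1]))
  expect_warning(detect_holes(matrix(5, 50, 50)), "no holes")
})

test_that("square summaries average sampled holes with bounded statistics", {
  f <- matrix(40, 210, 210)
  pr <- simulate_em_square(f, square_um = 21, noise_sd = 0, foil_nm = 40)
  tm <- thickness_map(pr)
  sm <- square_summary(tm, attr(pr, "holes"), n_holes = 10, seed = 1)
  expect_equal(length(sm$hole_means), 10)
  expect_equal(sm$mean, 40, tolerance = 1e-9)
  expect_equal(sm$sd, 0, tolerance = 1e-9)
  # non-uniform field: different seeds pick different holes, both bounded
  f2 <- sample_thickness_field(3, seed = 5, n_px = 210)
  pr2 <- simulate_em_square(f2, square_um = 21, noise_sd = 0)
  tm2 <- thickness_map(pr2)
  s1 <- square_summary(tm2, attr(pr2, "holes"), seed = 1)
  s2 <- square_summary(tm2, attr(pr2, "holes"), seed = 2)
  expect_false(identical(s1$hole_means, s2$hole_means))
  for (s in list(s1, s2)) {
    expect_gte(s$mean, min(s$hole_means))
    expect_lte(s$mean, max(s$hole_means))
    expect_gte(s$sd, 0)
  }
  expect_warning(square_summary(tm2, attr(pr2, "holes")[1:4, ], n_holes = 10),
                 "using all")
})
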