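test_that("injected grid angles are recovered within half a degree", {
  for (a in c(10, -17.5, 33)) {
    ig <- render_interferogram(build_scene(magnification = 5, angle = a,
                                           seed = 2), noise_sd = 0.02, seed = 1)
    est <- estimate_grid_angle(ig)
    expect_false(est$low_confidence)
    expect_lt(abs(est$angle - a), 0.5)
  }
})

test_that("an axis-aligned grid estimates to zero and 100 deg folds to 10", {
  ig0 <- render_interferogram(build_scene(magnification = 5, angle = 0,
                                          seed = 3), noise_sd = 0.02, seed = 1)
  expect_lte(abs(estimate_grid_angle(ig0)$angle), 0.25)
  sc <- build_scene(magnification = 5, angle = 100, seed = 3)
  expect_equal(sc$angle, 10) # 90-degree mesh symmetry
  ig <- render_interferogram(sc, noise_sd = 0.02, seed = 1)
  expect_lt(abs(estimate_grid_angle(ig)$angle - 10), 0.5)
})

test_that("estimation is equivariant under the injected rotation", {
  for (s in 1:4) {
    base <- 5 * s - 12
    delta <- 7
    e1 <- estimate_grid_angle(render_interferogram(
      build_scene(magnification = 5, angle = base, seed = s),
      noise_sd = 0.02, seed = 1))$angle
    e2 <- estimate_grid_angle(render_interferogram(
      build_scene(magnification = 5, angle = base + delta, seed = s),
      noise_sd = 0.02, seed = 1))$angle
    expect_lt(abs((e2 - e1) - delta), 0.5)
  }
})

test_that("rotation to axis is invertible and composes with estimation", {
  ig <- cached_render(5, 22)
  # angle 0 returns the identical image
  r0 <- rotate_to_axis(ig$image, 0)
  expect_equal(r0, ig$image, ignore_attr = TRUE)
  # rotate then estimate gives ~0 (idempotence of the deskew)
  est <- estimate_grid_angle(ig)
  rot <- rotate_to_axis(ig, est$angle)
  expect_lte(abs(estimate_grid_angle(rot)$angle), 0.5)
  # round trip: rotate by theta then -theta recovers a band-limited image
  # within interpolation error (< 1% of range in the centre region)
  g <- seq(0, 4 * pi, length.out = 256)
  smooth <- 0.5 + 0.25 * outer(sin(g), cos(g)) + 0.2 * outer(g, g) / (4 * pi)^2
  simg <- array(rep(pmin(smooth, 1), 3), c(256, 256, 3))
  fwd <- rotate_to_axis(simg, 15)
  back <- rotate_to_axis(fwd, -15)
  hb <- dim(back)[1]; wb <- dim(back)[2]
  r_off <- floor((hb - 256) / 2); c_off <- floor((wb - 256) / 2)
  centre <- 60:200
  orig <- simg[centre, centre, ]
  rec <- back[centre + r_off, centre + c_off, ]
  expect_lt(mean(abs(rec - orig)), 0.01)
})

test_that("a featureless image returns angle zero with a low-confidence flag", {
  est <- estimate_grid_angle(array(0.1, c(96, 96, 3)))
  expect_true(est$low_confidence)
  expect_equal(est$angle, 0)
})

test_that("points map correctly into the rotated frame", {
  img <- array(0, c(120, 180, 3))
  img[40, 150, ] <- 1
  for (ang in c(20, -35)) {
    rot <- rotate_to_axis(img, ang)
    hit <- which(rot[, , 1] == max(rot[, , 1]), arr.ind = TRUE)[1, ]
    pred <- map_points_to_rotated(matrix(c(40, 150), 1), attr(rot, "rotation"))
    expect_lt(abs(pred[1] - hit[1]), 2)
    expect_lt(abs(pred[2] - hit[2]), 2)
  }
})
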