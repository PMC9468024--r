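test_that("a uniform class-1 square renders with spatially constant colour", {
  model <- class_model(bins = list(c(11, 15), c(20, 50), c(50, 70), c(70, 100)),
                       spread = c(0, 3, 4, 5))
  sc <- build_scene(magnification = 5, angle = 0, labels = 1, model = model,
                    render_holes = FALSE, seed = 2)
  ig <- render_interferogram(sc, noise_sd = 0, seed = 1)
  sq <- ig$squares[ig$squares$complete, ][1, ]
  rr <- (sq$row0 + 2):(sq$row1 - 1)
  cc <- (sq$col0 + 2):(sq$col1 - 1)
  for (ch in 1:3) expect_equal(stats::sd(ig$image[rr, cc, ch]), 0)
})

test_that("the class-4 droplet profile matches the 1-D thin-film oracle", {
  sc <- build_scene(magnification = 10, angle = 0, labels = 4,
                    render_holes = FALSE, seed = 6)
  ig <- render_interferogram(sc, noise_sd = 0, seed = 1)
  sq <- ig$squares[ig$squares$complete, ][1, ]
  ci <- which(sc$cells$iu == sq$iu & sc$cells$iv == sq$iv)
  prm <- sc$params[[ci]]
  g <- sc$grid; ps <- sc$pixel_size
  open_w <- g$pitch - g$bar_width
  h <- sc$dim[1]; w <- sc$dim[2]
  # image row through the droplet centre (angle 0 geometry)
  v0 <- sq$iv * g$pitch + g$bar_width / 2 + prm$droplet$b0 * open_w
  r <- round((v0 - sc$offset[2]) / ps + h / 2 + 0.5)
  cols <- (sq$col0 + 1):sq$col1
  u <- (cols - 0.5 - w / 2) * ps + sc$offset[1]
  a <- (u - sq$iu * g$pitch - g$bar_width / 2) / open_w
  b <- ((r - 0.5 - h / 2) * ps + sc$offset[2] - sq$iv * g$pitch -
          g$bar_width / 2) / open_w
  keep <- a > 0.01 & a < 0.99
  # oracle: film reflectance evaluated along the 1-D thickness profile
  t_prof <- icescreen:::eval_square_field(a[keep], rep(b, sum(keep)), prm)
  st <- film_stack()
  rb <- band_reflectance(t_prof, wavelength_set(), st)
  gain <- 0.85 / (abs(st$r1) + abs(st$r2))^2
  predicted <- pmin(pmax(gain * rb + 0.12, 0), 1)
  for (ch in 1:3) {
    expect_equal(ig$image[r, cols[keep], ch], predicted[, ch],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # at least two full fringe periods across the droplet (blue channel)
  prof <- ig$image[r, cols[keep], 1]
  reversals <- sum(abs(diff(sign(diff(prof)))) > 0 &
                     abs(diff(prof, lag = 2)) > 0.05)
  expect_gte(reversals, 4)
})

test_that("rendering is bit-reproducible for a fixed scene and seed", {
  ig1 <- render_interferogram(build_scene(magnification = 5, seed = 4),
                              noise_sd = 0.02, seed = 9)
  ig2 <- render_interferogram(build_scene(magnification = 5, seed = 4),
                              noise_sd = 0.02, seed = 9)
  expect_identical(ig1$image, ig2$image)
  expect_identical(ig1$squares, ig2$squares)
  ig3 <- render_interferogram(build_scene(magnification = 5, seed = 4),
                              noise_sd = 0.02, seed = 10)
  expect_false(identical(ig1$image, ig3$image))
})

test_that("scene geometry errors and mask consistency", {
  expect_error(build_scene(magnification = 5, dim = c(64, 64), angle = 30,
                           seed = 1), "too small")
  ig <- cached_render(5, 21)
  expect_true(all(ig$tile_mask %in% c(0, 1)))
  # complete squares sit fully inside the raster with tile pixels at centre
  for (i in which(ig$squares$complete)) {
    s <- ig$squares[i, ]
    expect_equal(ig$tile_mask[round(s$center_row), round(s$center_col)], 1)
  }
  # bounding boxes are consistent with the masks
  for (i in seq_len(nrow(ig$squares))) {
    s <- ig$squares[i, ]
    expect_identical(dim(ig$square_masks[[i]]),
                     c(s$row1 - s$row0, s$col1 - s$col0))
  }
})
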