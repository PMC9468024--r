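test_that("datasets are written with images, masks and a manifest", {
  dir <- tempfile()
  ds <- make_dataset(2, magnification = 5, dim = c(256, 256), seed = 3,
                     dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_images, 2)
  for (i in 1:2) {
    expect_true(file.exists(file.path(dir, man$images$file[i])))
    expect_true(file.exists(file.path(dir, man$images$mask_file[i])))
  }
  img <- read_image(file.path(dir, man$images$file[1]))
  expect_identical(dim(img), c(256L, 256L, 3L))
  mask <- round(read_image(file.path(dir, man$images$mask_file[1]))[, , 1])
  expect_true(all(mask %in% c(0, 1)))
  unlink(dir, recursive = TRUE)
})

test_that("manifests are identical across identical calls", {
  d1 <- make_dataset(2, magnification = 5, dim = c(256, 256), seed = 5)
  d2 <- make_dataset(2, magnification = 5, dim = c(256, 256), seed = 5)
  expect_identical(d1$manifest, d2$manifest)
  d3 <- make_dataset(2, magnification = 5, dim = c(256, 256), seed = 6)
  expect_false(identical(d1$manifest, d3$manifest))
})

test_that("a pure class-2 mix labels every square 2", {
  ds <- make_dataset(1, class_mix = c(0, 0, 1, 0, 0), magnification = 5,
                     dim = c(320, 320), seed = 2)
  sq <- ds$manifest$images[[1]]$squares
  expect_true(all(sq$class == 2))
})

test_that("a uniform mix yields a near-uniform label histogram", {
  ds <- make_dataset(10, class_mix = rep(0.2, 5), magnification = 5,
                     dim = c(320, 320), seed = 11)
  classes <- unlist(lapply(ds$manifest$images, function(e) e$squares$class))
  n <- length(classes)
  expect_gte(n, 50)
  # each class frequency within 4 binomial standard errors of 0.2
  se <- sqrt(0.2 * 0.8 / n)
  for (k in 0:4) {
    expect_lt(abs(mean(classes == k) - 0.2), 4 * se + 1e-9)
  }
})

test_that("the tile corpus is reproducible and labelled consistently", {
  c1 <- make_tile_corpus(2, magnification = 5, seed = 8)
  c2 <- make_tile_corpus(2, magnification = 5, seed = 8)
  expect_identical(c1, c2)
  expect_equal(nrow(c1$features), length(c1$labels))
  expect_true(all(c1$labels %in% 0:4))
  # truth detections carry the generator labels
  ig <- cached_render(5, 21)
  dets <- truth_detections(ig)
  truth <- ig$squares[ig$squares$complete, ]
  expect_length(dets, nrow(truth))
  expect_equal(vapply(dets, function(d) attr(d, "class_label"), 0),
               truth$class)
})
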