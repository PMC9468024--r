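rot90_crop <- function(crop) {
  out <- array(0, dim(crop))
  for (ch in 1:3) out[, , ch] <- t(crop[dim(crop)[1]:1, , ch])
  out
}

test_that("tile crops come out fixed-size, ordered, with degenerates rejected", {
  ig <- cached_render(5, 21)
  dets <- postprocess_mask(segment_tiles(ig))
  # border slivers below the minimum size are skipped with a warning
  cr <- suppressWarnings(extract_tile_crops(ig, dets, size = 64))
  expect_equal(length(cr$crops), length(cr$ids))
  expect_equal(cr$ids, sort(cr$ids))
  for (c_ in cr$crops) {
    expect_identical(dim(c_), c(64L, 64L, 3L))
    expect_true(all(c_ >= 0 & c_ <= 1))
  }
  # degenerate 1-px detection is skipped with a warning
  tiny <- structure(list(id = 99L, bbox = c(row0 = 5L, col0 = 5L, row1 = 6L,
                                            col1 = 6L),
                         mask = matrix(1, 1, 1), area = 1, aspect = 1,
                         touches_border = FALSE), class = "tile_detection")
  expect_warning(cr2 <- extract_tile_crops(ig, list(tiny)), "skipped")
  expect_length(cr2$crops, 0)
  # empty detection list is not an error
  cr3 <- extract_tile_crops(ig, list())
  expect_length(cr3$crops, 0)
})

test_that("classification returns a valid probability distribution", {
  model <- small_classifier()
  corp <- small_corpus()
  for (i in c(1, 7, 20)) {
    res <- classify_tile(corp$crops[[i]], model)
    expect_length(res$probabilities, 5)
    expect_equal(sum(res$probabilities), 1, tolerance = 1e-6)
    expect_true(all(res$probabilities >= 0))
    expect_equal(res$confidence, max(res$probabilities))
    expect_equal(res$class, which.max(res$probabilities) - 1L)
    expect_equal(res$name, ice_classes()$name[res$class + 1L])
  }
})

test_that("a 40 nm uniform tile classifies as optimal across seeded repeats", {
  corp <- benchmark_corpus()
  model40 <- class_model(bins = list(c(6, 20), c(36, 44), c(50, 70), c(70, 100)),
                         spread = c(1.5, 1, 4, 5))
  sc <- build_scene(magnification = 5, angle = 0, labels = 2, model = model40,
                    seed = 41)
  ig <- render_interferogram(sc, noise_sd = 0.02, seed = 41)
  dets <- truth_detections(ig)
  crop <- extract_tile_crops(ig, dets[1])$crops[[1]]
  hits <- 0
  for (s in 1:20) {
    m <- train_classifier(corp$features, corp$labels, train_config(seed = s))
    if (classify_tile(crop, m)$class == 2L) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("tiles with punched-hole defects classify as bad", {
  model_hole <- class_model(defect_types = "hole", defect_weights = 1)
  sc <- build_scene(magnification = 5, angle = 0, labels = 0,
                    model = model_hole, seed = 43)
  ig <- render_interferogram(sc, noise_sd = 0.02, seed = 43)
  dets <- truth_detections(ig)[1:3]
  cr <- extract_tile_crops(ig, dets)
  model <- benchmark_classifier()
  for (crop in cr$crops) {
    expect_equal(classify_tile(crop, model)$class, 0L)
  }
})

test_that("training is reproducible and errors on missing classes", {
  corp <- small_corpus()
  m1 <- train_classifier(corp$features, corp$labels, train_config(seed = 3))
  m2 <- train_classifier(corp$features, corp$labels, train_config(seed = 3))
  expect_identical(m1$validation_accuracy, m2$validation_accuracy)
  expect_identical(m1$W, m2$W)
  sub <- corp$labels != 4
  expect_error(train_classifier(corp$features[sub, ], corp$labels[sub]),
               "missing class")
  m3 <- train_classifier(corp$features[sub, ], corp$labels[sub],
                         classes = 0:3)
  expect_s3_class(m3, "ice_classifier")
  # an absent class still gets a (zero) slot in the probability vector
  res <- classify_tile(corp$features[1, ], m3)
  expect_equal(res$probabilities[5], 0)
})

test_that("one example per class is memorised perfectly", {
  corp <- small_corpus()
  idx <- vapply(0:4, function(k) which(corp$labels == k)[1], 0L)
  X <- corp$features[idx, ]
  m <- train_classifier(X, 0:4, train_config(seed = 1, batch_size = 1))
  preds <- vapply(seq_len(5), function(i) classify_tile(X[i, ], m)$class, 0L)
  expect_equal(preds, 0:4)
  expect_equal(m$validation_accuracy, 1)
})

test_that("class predictions are stable under 90-degree crop rotations", {
  corp <- small_corpus()
  model <- small_classifier()
  n <- min(60, length(corp$crops))
  pred0 <- vapply(corp$crops[1:n], function(cr) classify_tile(cr, model)$class, 0L)
  pred90 <- vapply(corp$crops[1:n],
                   function(cr) classify_tile(rot90_crop(cr), model)$class, 0L)
  acc0 <- mean(pred0 == corp$labels[1:n])
  acc90 <- mean(pred90 == corp$labels[1:n])
  expect_lte(abs(acc0 - acc90), 0.02)
})

test_that("confidence histograms tally assigned-class probabilities", {
  mk <- function(class, conf) {
    p <- rep((1 - conf) / 4, 5); p[class + 1] <- conf
    structure(list(class = class, name = ice_classes()$name[class + 1],
                   probabilities = p, confidence = conf),
              class = "class_result")
  }
  # all-confident results spike in the top bin
  res <- lapply(0:4, mk, conf = 1.0)
  h <- confidence_histograms(res, breaks = 10)
  for (nm in names(h)) expect_equal(h[[nm]]$count[10], 1)
  # uniform probability vectors mass at 0.2
  res2 <- replicate(5, mk(1, 0.2), simplify = FALSE)
  h2 <- confidence_histograms(res2, breaks = 10)
  expect_equal(h2[["too thin"]]$count[2], 5) # bin (0.1, 0.2]
  expect_equal(sum(h2[["optimal"]]$count), 0)
  # 100 random results match a brute-force tally
  confs <- icescreen:::with_seed(9, stats::runif(100, 0.2, 1))
  classes <- icescreen:::with_seed(10, sample(0:4, 100, replace = TRUE))
  res3 <- mapply(mk, classes, confs, SIMPLIFY = FALSE)
  h3 <- confidence_histograms(res3, breaks = 20)
  for (k in 0:4) {
    nm <- ice_classes()$name[k + 1]
    expect_equal(sum(h3[[nm]]$count), sum(classes == k))
    edges <- seq(0, 1, length.out = 21)
    brute <- table(cut(confs[classes == k], edges, include.lowest = TRUE))
    expect_equal(h3[[nm]]$count, as.integer(brute))
  }
  expect_identical(confidence_histograms(list()), list())
})
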