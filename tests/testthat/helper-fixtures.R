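# Shared fixtures, built once per test run and memoised. The benchmark
# corpus and classifier are the expensive ones; only tests that need them
# trigger their construction.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Labelled tile corpus at the benchmark scale: >= 2000 tiles over the
# image seed list 1..10, uniform class mix, default thickness bins.
benchmark_corpus <- function() {
  memo("benchmark_corpus", function() {
    chunks <- lapply(1:10, function(s) {
      make_tile_corpus(12, class_mix = rep(0.2, 5), magnification = 5,
                       seed = s)
    })
    list(features = do.call(rbind, lapply(chunks, `[[`, "features")),
         labels = unlist(lapply(chunks, `[[`, "labels")))
  })
}

benchmark_classifier <- function() {
  memo("benchmark_classifier", function() {
    corp <- benchmark_corpus()
    train_classifier(corp$features, corp$labels, train_config(seed = 1))
  })
}

# Small corpus for unit tests that just need a working classifier quickly.
small_corpus <- function() {
  memo("small_corpus", function() {
    make_tile_corpus(8, class_mix = rep(0.2, 5), magnification = 5,
                     seed = 77, return_crops = TRUE)
  })
}

small_classifier <- function() {
  memo("small_classifier", function() {
    corp <- small_corpus()
    train_classifier(corp$features, corp$labels, train_config(seed = 2))
  })
}

# One rendered interferogram per (magnification, seed), cached.
cached_render <- function(magnification, seed, noise_sd = 0.02, ...) {
  key <- sprintf("ig_%s_%s_%s", magnification, seed, noise_sd)
  memo(key, function() {
    render_interferogram(
      build_scene(magnification = magnification, seed = seed, ...),
      noise_sd = noise_sd, seed = seed)
  })
}

# Match analysed tiles to generator truth by square centres mapped through
# the report's rotation; returns data.frame(true_class, pred_class).
match_tiles_to_truth <- function(report, ig, max_dist = 20) {
  truth <- ig$squares[ig$squares$complete, , drop = FALSE]
  if (!nrow(truth) || !nrow(report$tiles)) {
    return(data.frame(true_class = integer(0), pred_class = integer(0)))
  }
  rot <- report$rotation
  if (is.list(rot) && !is.null(rot$in_dim)) {
    rot$in_dim <- as.numeric(unlist(rot$in_dim))
    rot$out_dim <- as.numeric(unlist(rot$out_dim))
  }
  tc <- map_points_to_rotated(cbind(truth$center_row + 0.5,
                                    truth$center_col + 0.5), rot)
  dc <- cbind((report$tiles$row0 + report$tiles$row1) / 2,
              (report$tiles$col0 + report$tiles$col1) / 2)
  rows <- lapply(seq_len(nrow(truth)), function(j) {
    d2 <- (dc[, 1] - tc[j, 1])^2 + (dc[, 2] - tc[j, 2])^2
    k <- which.min(d2)
    if (sqrt(d2[k]) > max_dist) return(NULL)
    data.frame(true_class = truth$class[j], pred_class = report$tiles$class[k])
  })
  do.call(rbind, c(rows, list(data.frame(true_class = integer(0),
                                         pred_class = integer(0)))))
}
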