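#' Extract fixed-size normalised crops for the detected tiles
#'
#' Cuts each detection's bounding box out of the image, masks pixels
#' outside the detection with the background fill (relevant for
#' border-flagged partial tiles), and resamples the crop to a square of
#' side `size`. Intensities stay on the [0, 1] scale. Detections smaller
#' than `min_px` on a side are rejected with a warning.
#'
#' @param image An `interferogram` or `H x W x 3` array.
#' @param detections List of detections from [postprocess_mask()].
#' @param size Output crop side in px.
#' @param min_px Minimum detection side in px.
#' @param fill Background fill value.
#' @return A list with `crops` (list of `size x size x 3` arrays) and
#'   `ids` (the detection ids, in detection order).
#' @export
extract_tile_crops <- function(image, detections, size = 128L, min_px = 8L,
                               fill = 0.5) {
  img <- as_image_array(image)
  crops <- list(); ids <- integer(0)
  for (d in detections) {
    bb <- d$bbox
    hgt <- bb[["row1"]] - bb[["row0"]]; wid <- bb[["col1"]] - bb[["col0"]]
    if (hgt < min_px || wid < min_px) {
      warning(sprintf("tile %s smaller than %d px; skipped", d$id, min_px))
      next
    }
    sub <- img[(bb[["row0"]] + 1L):bb[["row1"]],
               (bb[["col0"]] + 1L):bb[["col1"]], , drop = FALSE]
    if (d$touches_border || any(d$mask == 0)) {
      m <- d$mask
      for (ch in 1:3) {
        plane <- sub[, , ch]
        plane[m == 0] <- fill
        sub[, , ch] <- plane
      }
    }
    crop <- from_ebimage(EBImage::resize(as_ebimage(sub), w = size, h = size))
    crops[[length(crops) + 1L]] <- clamp01(crop)
    ids <- c(ids, d$id)
  }
  list(crops = crops, ids = ids)
}

# Interference-pattern features of one crop. All features are (close to)
# invariant under 90-degree rotations: channel statistics, dark-defect
# evidence from a 5x5 box-smoothed brightness, centre-versus-edge contrast,
# fringe counts along the ring-averaged radial profile, and gradient
# energy.
tile_features <- function(crop) {
  n <- dim(crop)[1L]
  b <- brightness_of(crop)
  s <- saturation_of(crop)
  bb <- box_mean(b, 2L)
  ctr <- (n + 1) / 2
  rr <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  rbin <- pmin(floor(rr) + 1L, floor(n / 2))
  center <- rr < 0.25 * n
  edge <- rr > 0.4 * n & rr < 0.5 * n

  fringe_count <- function(plane) {
    prof <- as.vector(rowsum(as.vector(plane), as.vector(rbin)) /
                        tabulate(as.vector(rbin)))
    prof <- prof[!is.na(prof)]
    if (length(prof) < 5L) return(0)
    # count direction reversals with at least 0.04 prominence
    ext <- 0
    last <- prof[1L]
    dir <- 0
    for (v in prof[-1L]) {
      if (dir == 0) dir <- sign(v - last)
      if (dir > 0 && v < last - 0.04) { ext <- ext + 1; dir <- -1 }
      if (dir < 0 && v > last + 0.04) { ext <- ext + 1; dir <- 1 }
      if ((dir > 0 && v > last) || (dir < 0 && v < last)) last <- v
    }
    ext
  }

  grad <- mean(abs(diff(b))) + mean(abs(t(diff(t(b)))))
  q <- stats::quantile(b, c(0.1, 0.9), names = FALSE)
  c(
    mean_R = mean(crop[, , 1L]), mean_G = mean(crop[, , 2L]),
    mean_B = mean(crop[, , 3L]),
    sd_R = stats::sd(crop[, , 1L]), sd_G = stats::sd(crop[, , 2L]),
    sd_B = stats::sd(crop[, , 3L]),
    bright_mean = mean(b), bright_sd = stats::sd(b),
    sat_mean = mean(s), sat_sd = stats::sd(s),
    frac_black = mean(b < 0.05), frac_dark = mean(b < 0.12),
    min_box_bright = min(bb), frac_box_black = mean(bb < 0.05),
    box_dip = stats::median(bb) - min(bb),
    box_dip_rel = (stats::median(bb) - min(bb)) / (stats::median(bb) + 0.02),
    center_edge = mean(b[center]) - mean(b[edge]),
    fringes_R = fringe_count(crop[, , 1L]),
    fringes_G = fringe_count(crop[, , 2L]),
    fringes_B = fringe_count(crop[, , 3L]),
    grad_energy = grad,
    bright_p90_p10 = q[2L] - q[1L],
    center_R = mean(crop[, , 1L][center]),
    center_G = mean(crop[, , 2L][center]),
    center_B = mean(crop[, , 3L][center])
  )
}

#' Train the five-class ice-quality tile classifier
#'
#' Trains a compact multinomial softmax classifier on interference-pattern
#' features extracted from labelled tile crops, using stochastic gradient
#' descent with momentum, L2 penalty and the piecewise learning-rate
#' schedule (one schedule tick per epoch; see [lr_schedule()]). The split
#' is stratified by class; overall and per-class validation accuracies are
#' reported, and results are reproducible per seed.
#'
#' @param crops List of `size x size x 3` crop arrays, or a precomputed
#'   feature matrix (rows = tiles).
#' @param labels Integer class labels 0-4, one per crop.
#' @param config A [train_config()].
#' @param classes Classes the model must cover; a class in `classes` with
#'   no training example raises a missing-class error. Defaults to all
#'   five.
#' @return An object of class `ice_classifier` with weights, feature
#'   scaling, `validation_accuracy`, `per_class_accuracy` and the training
#'   trace.
#' @export
train_classifier <- function(crops, labels, config = train_config(),
                             classes = 0:4) {
  if (!inherits(config, "train_config")) stop("`config` must be a train_config", call. = FALSE)
  labels <- as.integer(labels)
  if (any(!labels %in% 0:4)) stop("labels must be classes 0-4", call. = FALSE)
  present <- sort(unique(labels))
  missing <- setdiff(classes, present)
  if (length(missing)) {
    stop(sprintf("missing class(es) in training data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  present <- sort(unique(c(classes, present)))
  if (length(labels) < 2L || length(present) < 2L) {
    stop("need at least 2 examples of at least 2 classes", call. = FALSE)
  }
  X <- if (is.matrix(crops)) crops else
    t(vapply(crops, tile_features, numeric(length(tile_features(crops[[1L]])))))
  if (nrow(X) != length(labels)) stop("crops and labels differ in length", call. = FALSE)
  y <- match(labels, present)
  with_seed(config$seed, {
    mu <- colMeans(X); sd <- pmax(apply(X, 2L, stats::sd), 1e-8)
    Xs <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
    spl <- stratified_split(y, config$val_split)
    # Degenerate corpora (single example per class) cannot be split; the
    # model is then validated on its training data (memorisation check).
    if (!length(spl$val)) spl$val <- spl$train
    fit <- softmax_sgd(Xs[spl$train, , drop = FALSE], y[spl$train],
                       length(present), config,
                       val = list(X = Xs[spl$val, , drop = FALSE], y = y[spl$val]))
    pv <- softmax_predict(fit$W, Xs[spl$val, , drop = FALSE])
    pred <- max.col(pv)
    per_class <- vapply(seq_along(present), function(k) {
      idx <- y[spl$val] == k
      if (!any(idx)) NA_real_ else mean(pred[idx] == k)
    }, 0)
    names(per_class) <- as.character(present)
    structure(list(
      W = fit$W, feature_mean = mu, feature_sd = sd, classes = present,
      validation_accuracy = mean(pred == y[spl$val]),
      per_class_accuracy = per_class,
      trace = fit$trace, config = config
    ), class = "ice_classifier")
  })
}

#' Classify one tile crop
#'
#' @param crop A `size x size x 3` crop array (or a named feature vector).
#' @param model An [train_classifier()] model.
#' @return An object of class `class_result`: `class` (0-4), `name`,
#'   `probabilities` (length 5, summing to 1; absent training classes get
#'   probability 0), `confidence` (max probability).
#' @export
classify_tile <- function(crop, model) {
  if (!inherits(model, "ice_classifier")) {
    stop("`model` must be an ice_classifier", call. = FALSE)
  }
  x <- if (is.numeric(crop) && is.null(dim(crop))) crop else tile_features(crop)
  if (length(x) != length(model$feature_mean)) {
    stop("crop features do not match the model", call. = FALSE)
  }
  xs <- (x - model$feature_mean) / model$feature_sd
  p <- softmax_predict(model$W, matrix(xs, 1L))
  probs <- numeric(5L)
  probs[model$classes + 1L] <- p
  cls <- model$classes[which.max(p)]
  structure(list(class = cls,
                 name = ice_classes()$name[cls + 1L],
                 probabilities = probs,
                 confidence = max(p)), class = "class_result")
}

#' Per-class histograms of assigned-class probability
#'
#' For each predicted class, histograms the probability the classifier
#' assigned to that class (its confidence), the standard summary of how
#' decisively tiles are classified.
#'
#' @param results List of `class_result` objects.
#' @param breaks Number of equal-width bins over [0, 1].
#' @return A list with one `data.frame(lower, upper, count)` per class
#'   name; classes without results get all-zero counts. Empty input gives
#'   an empty list.
#' @export
confidence_histograms <- function(results, breaks = 20L) {
  if (!length(results)) return(list())
  edges <- seq(0, 1, length.out = breaks + 1L)
  out <- list()
  classes <- ice_classes()
  for (k in 0:4) {
    conf <- vapply(Filter(function(r) r$class == k, results),
                   function(r) r$confidence, 0)
    # right-closed bins (lo, hi], lowest bin closed at 0
    counts <- if (length(conf)) {
      tabulate(pmin(pmax(ceiling(conf * breaks), 1L), breaks), breaks)
    } else integer(breaks)
    out[[classes$name[k + 1L]]] <- data.frame(
      lower = edges[-length(edges)], upper = edges[-1L], count = counts)
  }
  out
}
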