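# Per-pixel features for the learned segmentation path: the three channel
# values, brightness, channel spread, and a local brightness SD that
# distinguishes the flat metal bars from textured film.
pixel_features <- function(img) {
  b <- brightness_of(img)
  s <- saturation_of(img)
  mu <- box_mean(b, 2L)
  mu2 <- box_mean(b^2, 2L)
  local_sd <- sqrt(pmax(mu2 - mu^2, 0))
  cbind(R = as.vector(img[, , 1L]), G = as.vector(img[, , 2L]),
        B = as.vector(img[, , 3L]), bright = as.vector(b),
        sat = as.vector(s), local_sd = as.vector(local_sd))
}

#' Train the pixel-wise tile/background segmenter
#'
#' Trains a logistic pixel classifier (tile vs background) on labelled
#' images by stochastic gradient descent with momentum, L2 penalty and the
#' piecewise learning-rate schedule of [lr_schedule()] (one schedule tick
#' per epoch). A random subsample of pixels per image forms the training
#' pool; validation pixel accuracy is recorded at the configured cadence.
#' This is a deliberately compact learned alternative to the classical
#' path of [segment_tiles()]; both honour the same contract.
#'
#' @param dataset A list of `list(image, mask)` pairs (>= 2 images), e.g.
#'   rendered scenes with their ground-truth masks.
#' @param config A [train_config()].
#' @param pixels_per_image Number of pixels sampled from each image.
#' @return An object of class `seg_model`: weights, feature scaling, the
#'   validation trace (`epoch`, `lr`, `val_accuracy`), and the config.
#' @export
train_segmenter <- function(dataset, config = train_config(),
                            pixels_per_image = 4000L) {
  if (!is.list(dataset) || length(dataset) < 2L) {
    stop("`dataset` must hold at least 2 labelled images", call. = FALSE)
  }
  if (!inherits(config, "train_config")) stop("`config` must be a train_config", call. = FALSE)
  with_seed(config$seed, {
    feats <- list(); labs <- list()
    for (i in seq_along(dataset)) {
      img <- as_image_array(dataset[[i]]$image)
      mask <- dataset[[i]]$mask
      if (!is_binary_mask(mask) || !identical(dim(mask), dim(img)[1:2])) {
        stop("each dataset entry needs a 0/1 mask matching its image", call. = FALSE)
      }
      Fi <- pixel_features(img)
      pick <- sample.int(nrow(Fi), min(pixels_per_image, nrow(Fi)))
      feats[[i]] <- Fi[pick, , drop = FALSE]
      labs[[i]] <- as.vector(mask)[pick] + 1L # 1 = background, 2 = tile
    }
    X <- do.call(rbind, feats)
    y <- unlist(labs)
    if (length(unique(y)) < 2L) {
      stop("training pixels must contain both tile and background", call. = FALSE)
    }
    mu <- colMeans(X); sd <- pmax(apply(X, 2L, stats::sd), 1e-8)
    Xs <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
    spl <- stratified_split(y, config$val_split)
    fit <- softmax_sgd(Xs[spl$train, , drop = FALSE], y[spl$train], 2L, config,
                       val = list(X = Xs[spl$val, , drop = FALSE], y = y[spl$val]))
    structure(list(W = fit$W, feature_mean = mu, feature_sd = sd,
                   trace = fit$trace, config = config),
              class = "seg_model")
  })
}

# Apply a trained seg_model to an image; returns a 0/1 tile mask.
predict_seg_model <- function(model, img) {
  Fi <- pixel_features(img)
  Xs <- sweep(sweep(Fi, 2L, model$feature_mean), 2L, model$feature_sd, "/")
  P <- softmax_predict(model$W, Xs)
  matrix(as.numeric(P[, 2L] > 0.5), dim(img)[1L], dim(img)[2L])
}
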