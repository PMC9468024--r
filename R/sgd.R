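#' Piecewise-constant learning-rate schedule
#'
#' Effective learning rate after `k` schedule ticks:
#' `alpha * drop_factor ^ floor(k / drop_every)`. With the defaults
#' (alpha = 0.001, a 30% drop every 4th tick) the rate after 8 ticks is
#' `0.001 * 0.7^2`. Training functions in this package advance the schedule
#' once per epoch (full pass over the training set); the tick unit is a
#' configuration choice, not part of this function.
#'
#' @param k Tick index (vectorised, >= 0).
#' @param alpha Initial learning rate.
#' @param drop_factor Multiplicative factor applied at each drop (in (0,1)).
#' @param drop_every Number of ticks between drops (>= 1).
#' @return Learning rate(s).
#' @export
#' @examples
#' lr_schedule(8) # 0.001 * 0.49
lr_schedule <- function(k, alpha = 0.001, drop_factor = 0.7, drop_every = 4L) {
  stopifnot_scalar(alpha, "alpha", 0, strict = TRUE)
  if (drop_factor <= 0 || drop_factor >= 1) {
    stop("`drop_factor` must be in (0, 1)", call. = FALSE)
  }
  if (drop_every < 1) stop("`drop_every` must be >= 1", call. = FALSE)
  alpha * drop_factor^(floor(k / drop_every))
}

#' Training configuration for the SGD-based models
#'
#' Shared hyper-parameters of the segmentation and classification trainers:
#' stochastic gradient descent with momentum, L2 weight penalty and the
#' piecewise learning-rate schedule of [lr_schedule()]. Defaults follow the
#' published recipe: alpha = 0.001 dropped by 30% each 4th schedule tick,
#' L2 = 0.005, momentum 0.9, validation each 4th tick.
#'
#' @param alpha Initial learning rate (> 0).
#' @param drop_factor Learning-rate drop factor in (0, 1).
#' @param drop_every Ticks between drops.
#' @param l2 L2 penalty on weights.
#' @param momentum Momentum coefficient in [0, 1).
#' @param val_every Validate each `val_every`-th tick.
#' @param epochs Number of epochs (schedule ticks).
#' @param batch_size Mini-batch size.
#' @param val_split Held-out validation fraction in (0, 1).
#' @param seed RNG seed for init, shuffling and the split.
#' @return An object of class `train_config`.
#' @export
train_config <- function(alpha = 0.001, drop_factor = 0.7, drop_every = 4L,
                         l2 = 0.005, momentum = 0.9, val_every = 4L,
                         epochs = 40L, batch_size = 8L, val_split = 0.2,
                         seed = 1L) {
  stopifnot_scalar(alpha, "alpha", 0, strict = TRUE)
  if (drop_factor <= 0 || drop_factor >= 1) stop("`drop_factor` must be in (0,1)", call. = FALSE)
  if (drop_every < 1 || val_every < 1) stop("cadences must be >= 1", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0,1)", call. = FALSE)
  if (val_split <= 0 || val_split >= 1) stop("`val_split` must be in (0,1)", call. = FALSE)
  structure(list(alpha = alpha, drop_factor = drop_factor,
                 drop_every = as.integer(drop_every), l2 = l2,
                 momentum = momentum, val_every = as.integer(val_every),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 val_split = val_split, seed = as.integer(seed)),
            class = "train_config")
}

# Multinomial softmax classifier trained by mini-batch SGD with momentum,
# L2 penalty (weights only, not biases) and the piecewise schedule. X is
# n x p (already standardised), y integer class ids 1..K. Returns weights
# [p+1, K] and a per-validation trace. `val` is an optional list(X, y).
softmax_sgd <- function(X, y, K, config, val = NULL) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p + 1L, K)
  V <- matrix(0, p + 1L, K)
  Xb <- cbind(1, X)
  trace <- list(epoch = integer(0), lr = numeric(0), val_accuracy = numeric(0),
                train_loss = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, config$alpha, config$drop_factor, config$drop_every)
    ord <- sample.int(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Z <- Xb[idx, , drop = FALSE] %*% W
      Z <- Z - apply(Z, 1L, max)
      P <- exp(Z); P <- P / rowSums(P)
      Yh <- matrix(0, length(idx), K)
      Yh[cbind(seq_along(idx), y[idx])] <- 1
      G <- crossprod(Xb[idx, , drop = FALSE], P - Yh) / length(idx)
      G[-1L, ] <- G[-1L, ] + config$l2 * W[-1L, ]
      V <- config$momentum * V - lr * G
      W <- W + V
    }
    if (epoch %% config$val_every == 0L || epoch == config$epochs) {
      Ztr <- Xb %*% W; Ztr <- Ztr - apply(Ztr, 1L, max)
      Ptr <- exp(Ztr); Ptr <- Ptr / rowSums(Ptr)
      loss <- -mean(log(pmax(Ptr[cbind(seq_len(n), y)], 1e-12)))
      va <- NA_real_
      if (!is.null(val)) {
        pv <- softmax_predict(W, val$X)
        va <- mean(max.col(pv) == val$y)
      }
      trace$epoch <- c(trace$epoch, epoch)
      trace$lr <- c(trace$lr, lr)
      trace$val_accuracy <- c(trace$val_accuracy, va)
      trace$train_loss <- c(trace$train_loss, loss)
    }
  }
  list(W = W, trace = as.data.frame(trace))
}

softmax_predict <- function(W, X) {
  Z <- cbind(1, X) %*% W
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z)
  P / rowSums(P)
}

# Stratified train/validation split; returns list(train, val) index vectors.
stratified_split <- function(y, val_split) {
  val <- integer(0)
  for (k in unique(y)) {
    idx <- which(y == k)
    n_val <- max(1L, round(length(idx) * val_split))
    if (n_val >= length(idx)) n_val <- length(idx) - 1L
    val <- c(val, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Serialise a trained model to a single versioned file
#'
#' @param model A model object from [train_segmenter()] or
#'   [train_classifier()].
#' @param path Destination file.
#' @export
write_model <- function(model, path) {
  payload <- list(format = "icescreen-model", format_version = 1L,
                  package_version = as.character(utils::packageVersion("icescreen")),
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the model object.
#' @export
read_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "icescreen-model")) {
    stop("not an icescreen model file", call. = FALSE)
  }
  payload$model
}
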