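# Internal helpers shared across modules.

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  invisible(x)
}

# Convert an [H, W] matrix or [H, W, 3] array (row = image row, top-left
# origin) to an EBImage Image and back. EBImage stores x (column) first.
as_ebimage <- function(a) {
  if (length(dim(a)) == 2L) {
    EBImage::Image(t(a))
  } else {
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = "Color")
  }
}

from_ebimage <- function(img) {
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

# Channel helpers for [H, W, 3] arrays.
brightness_of <- function(img) (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
saturation_of <- function(img) {
  pmax(img[, , 1L], img[, , 2L], img[, , 3L]) -
    pmin(img[, , 1L], img[, , 2L], img[, , 3L])
}

# Box-mean of a matrix with half-width `k` px via integral image; edges use
# the shrunken window. Used for defect evidence and pixel features.
box_mean <- function(m, k = 2L) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 1L, w + 1L)
  pad[-1L, -1L] <- m
  ii <- apply(apply(pad, 2L, cumsum), 1L, cumsum) # [w+1, h+1] transposed
  ii <- t(ii)
  r0 <- pmax(seq_len(h) - k - 1L, 0L); r1 <- pmin(seq_len(h) + k, h)
  c0 <- pmax(seq_len(w) - k - 1L, 0L); c1 <- pmin(seq_len(w) + k, w)
  s <- ii[r1 + 1L, c1 + 1L, drop = FALSE] - ii[r0 + 1L, c1 + 1L, drop = FALSE] -
    ii[r1 + 1L, c0 + 1L, drop = FALSE] + ii[r0 + 1L, c0 + 1L, drop = FALSE]
  n <- outer(r1 - r0, c1 - c0)
  s / n
}

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}
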