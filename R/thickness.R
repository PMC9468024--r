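#' Absolute ice thickness from a filtered/unfiltered EM pair
#'
#' Pixel-wise zero-loss thickness estimate
#' `t = lambda_inel * ln(I_t / I_zl)`, the exact inverse of the
#' [simulate_em_pair()] forward model. Pixels where either intensity is
#' non-positive are marked invalid; negative apparent thickness (possible
#' under noise) is clipped to 0 and flagged.
#'
#' @param pair An `em_pair`.
#' @return An object of class `thickness_map`: list with `thickness` (nm),
#'   `valid` (logical matrix) and `clipped` (logical matrix).
#' @export
#' @examples
#' pr <- simulate_em_pair(matrix(40, 4, 4), noise_sd = 0)
#' thickness_map(pr)$thickness[1, 1]
thickness_map <- function(pair) {
  if (!inherits(pair, "em_pair")) stop("`pair` must be an em_pair", call. = FALSE)
  if (!identical(dim(pair$unfiltered), dim(pair$filtered))) {
    stop("filtered and unfiltered images must have identical shapes", call. = FALSE)
  }
  valid <- pair$unfiltered > 0 & pair$filtered > 0
  t <- matrix(NA_real_, nrow(pair$unfiltered), ncol(pair$unfiltered))
  t[valid] <- pair$lambda_inel * log(pair$unfiltered[valid] / pair$filtered[valid])
  clipped <- valid & !is.na(t) & t < 0
  t[clipped] <- 0
  structure(list(thickness = t, valid = valid, clipped = clipped,
                 lambda_inel = pair$lambda_inel,
                 pixel_size_nm = pair$pixel_size_nm),
            class = "thickness_map")
}

#' Detect foil holes in a low-magnification EM image
#'
#' Holes through the support foil transmit more zero-loss electrons and
#' appear as bright discs in the filtered image. The detector thresholds
#' midway between the robust dark and bright levels, labels connected
#' components (4-connectivity), fits a circle to each (centroid and
#' area-equivalent radius) and keeps components whose radius matches the
#' expected hole radius within `tol`. Components touching the image border
#' (incomplete holes) are excluded. Fully deterministic.
#'
#' @param em_image Grayscale matrix (typically `pair$filtered`).
#' @param hole_radius_px Expected hole radius in px; `NULL` accepts any
#'   plausible disc (radius >= 2 px).
#' @param tol Relative radius tolerance.
#' @return data.frame with `row`, `col` (centre, 1-based px), `radius`
#'   and `area_px`; zero rows (with a warning) if nothing is found.
#' @export
detect_holes <- function(em_image, hole_radius_px = NULL, tol = 0.3) {
  if (!is.matrix(em_image)) stop("`em_image` must be a matrix", call. = FALSE)
  q <- stats::quantile(em_image, c(0.02, 0.98), names = FALSE)
  if (diff(q) < 1e-9) {
    warning("no holes found: image has no contrast")
    return(data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), area_px = numeric(0)))
  }
  thr <- mean(q)
  bright <- em_image > thr
  lab <- EBImage::bwlabel(as_ebimage(bright * 1))
  lab <- from_ebimage(lab)
  n <- max(lab)
  out <- list()
  h <- nrow(em_image); w <- ncol(em_image)
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    rad <- sqrt(area / pi)
    if (rad < 2) next
    if (any(idx[, 1] == 1 | idx[, 1] == h | idx[, 2] == 1 | idx[, 2] == w)) next
    if (!is.null(hole_radius_px) &&
        abs(rad - hole_radius_px) > tol * hole_radius_px) next
    # Reject clearly non-circular blobs: bbox fill factor of a disc ~ pi/4.
    fill <- area / ((diff(range(idx[, 1])) + 1) * (diff(range(idx[, 2])) + 1))
    if (fill < 0.55) next
    out[[length(out) + 1L]] <- data.frame(row = mean(idx[, 1]),
                                          col = mean(idx[, 2]),
                                          radius = rad, area_px = area)
  }
  if (!length(out)) {
    warning("no holes found")
    return(data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), area_px = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$row, res$col), , drop = FALSE]
}

#' Per-square ice-thickness summary over randomly sampled holes
#'
#' Reproduces the validation summary used to relate quality classes to
#' absolute thickness: sample `n_holes` detected foil holes at random
#' (without replacement), average the thickness map over each hole interior
#' (disc eroded by 2 px to avoid edge fringes), and report the mean and
#' standard deviation of the hole means.
#'
#' @param map A [thickness_map()].
#' @param holes data.frame from [detect_holes()] (or generator truth).
#' @param n_holes Number of holes to sample (default 10).
#' @param seed Seed for the hole draw.
#' @return A list of class `square_summary`: `hole_means` (nm),
#'   `mean` (nm), `sd` (nm), `holes_used`.
#' @export
square_summary <- function(map, holes, n_holes = 10L, seed = 1L) {
  if (!inherits(map, "thickness_map")) stop("`map` must be a thickness_map", call. = FALSE)
  if (nrow(holes) == 0L) stop("no holes available for the summary", call. = FALSE)
  if (nrow(holes) < n_holes) {
    warning(sprintf("only %d holes available; using all of them", nrow(holes)))
    pick <- seq_len(nrow(holes))
  } else {
    pick <- with_seed(seed, sample(nrow(holes), n_holes))
  }
  t <- map$thickness
  h <- nrow(t); w <- ncol(t)
  hole_means <- vapply(pick, function(i) {
    r0 <- holes$row[i]; c0 <- holes$col[i]
    rad <- max(holes$radius[i] - 2, 1)
    rr <- max(1L, floor(r0 - rad)):min(h, ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(w, ceiling(c0 + rad))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    vals <- t[rr, cc][d2 <= rad^2 & map$valid[rr, cc]]
    mean(vals)
  }, 0)
  structure(list(hole_means = hole_means, mean = mean(hole_means),
                 sd = stats::sd(hole_means), holes_used = holes[pick, ]),
            class = "square_summary")
}
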