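#' Estimate the in-plane grid rotation with a radon-transform criterion
#'
#' Projects a bar-likeness map of the image along candidate directions and
#' scores each direction by the variance of its projection profile: the
#' profile is sharpest (bars collapse onto narrow peaks) when the
#' projection direction is parallel to a bar axis. A coarse pass at
#' `coarse_step` degrees is refined around its optimum at
#' `angular_resolution`; the 90-degree mesh symmetry folds the result into
#' [-45, 45), and ties break toward the smaller absolute angle. On a
#' featureless image (no bar-like pixels or a flat score profile) the
#' estimate falls back to 0 degrees with `low_confidence = TRUE`.
#'
#' @param image An `interferogram`, `H x W x 3` array or grayscale matrix.
#' @param angular_resolution Fine search step in degrees.
#' @param coarse_step Coarse search step in degrees.
#' @return An object of class `grid_angle`: `angle` (degrees in [-45, 45)),
#'   `score_profile` (data.frame of candidate angle and score),
#'   `low_confidence`.
#' @export
#' @examples
#' ig <- render_interferogram(build_scene(magnification = 5, angle = 10,
#'                                        seed = 1), seed = 1)
#' estimate_grid_angle(ig)$angle
estimate_grid_angle <- function(image, angular_resolution = 0.25,
                                coarse_step = 2) {
  img <- as_image_array(image)
  b <- brightness_of(img)
  s <- saturation_of(img)
  cand <- s < 0.10 & b > 0.35
  if (mean(cand) < 0.01) {
    return(structure(list(angle = 0, score_profile = NULL,
                          low_confidence = TRUE), class = "grid_angle"))
  }
  bar_level <- stats::median(b[cand])
  m <- (s < 0.12 & abs(b - bar_level) < 0.18) * 1

  score_at <- function(phis) {
    vapply(phis, function(phi) radon_sharpness(m, phi), 0)
  }
  coarse <- seq(-45, 45 - coarse_step, by = coarse_step)
  sc <- score_at(coarse)
  best <- coarse[order(-sc, abs(coarse))][1L]
  fine <- seq(best - coarse_step, best + coarse_step, by = angular_resolution)
  fine <- ((fine + 45) %% 90) - 45
  sf <- score_at(fine)
  angle <- fine[order(-sf, abs(fine))][1L]
  flat <- stats::sd(c(sc, sf)) < 1e-12
  structure(list(
    angle = if (flat) 0 else angle,
    score_profile = data.frame(angle = c(coarse, fine), score = c(sc, sf)),
    low_confidence = flat
  ), class = "grid_angle")
}

# Variance of the column-sum projection of `m` after rotating it by -phi,
# i.e. the radon projection along direction phi, normalised by the rotated
# support to suppress the corner bias of the growing canvas.
radon_sharpness <- function(m, phi) {
  if (abs(phi) < 1e-12) {
    prof <- colMeans(m)
    return(stats::var(prof))
  }
  rm_ <- from_ebimage(EBImage::rotate(as_ebimage(m), -phi, bg.col = 0))
  rv <- from_ebimage(EBImage::rotate(as_ebimage(matrix(1, nrow(m), ncol(m))),
                                     -phi, bg.col = 0))
  cnt <- colSums(rv)
  keep <- cnt > 0.5 * max(cnt)
  prof <- colSums(rm_)[keep] / cnt[keep]
  stats::var(prof)
}

#' Rotate an image to axis alignment
#'
#' Bilinear rotation by `-angle` about the image centre, with a canvas
#' grown to contain the whole rotated frame and a fill value estimated from
#' the image border. Applying it with the angle from
#' [estimate_grid_angle()] aligns the grid bars with the raster axes. The
#' returned array carries a `rotation` attribute (`angle`, `in_dim`,
#' `out_dim`) so points can be mapped between the frames with
#' [map_points_to_rotated()].
#'
#' @param image An `interferogram` or image array.
#' @param angle Grid angle in degrees (as estimated).
#' @return The rotated `H' x W' x 3` array.
#' @export
rotate_to_axis <- function(image, angle) {
  img <- as_image_array(image)
  stopifnot_scalar(angle, "angle")
  if (angle == 0) {
    attr(img, "rotation") <- list(angle = 0, in_dim = dim(img)[1:2],
                                  out_dim = dim(img)[1:2])
    return(img)
  }
  border <- c(img[1L, , ], img[dim(img)[1L], , ], img[, 1L, ], img[, dim(img)[2L], ])
  bg <- stats::median(border)
  out <- from_ebimage(EBImage::rotate(as_ebimage(img), -angle,
                                      filter = "bilinear", bg.col = bg))
  out <- clamp01(out)
  attr(out, "rotation") <- list(angle = angle, in_dim = dim(img)[1:2],
                                out_dim = dim(out)[1:2])
  out
}

#' Map points from an image into its axis-aligned (rotated) frame
#'
#' @param points Two-column matrix or data.frame of `(row, col)` positions
#'   in the original image (1-based pixel centres).
#' @param rotation The `rotation` attribute of a [rotate_to_axis()] result.
#' @return A two-column matrix of positions in the rotated frame.
#' @export
map_points_to_rotated <- function(points, rotation) {
  pts <- as.matrix(points)
  th <- rotation$angle * pi / 180
  cin <- rotation$in_dim / 2
  cout <- rotation$out_dim / 2
  dr <- pts[, 1L] - cin[1L]; dc <- pts[, 2L] - cin[2L]
  cbind(row = cos(th) * dr - sin(th) * dc + cout[1L],
        col = sin(th) * dr + cos(th) * dc + cout[2L])
}
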