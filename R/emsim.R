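#' Simulate an energy-filtered / unfiltered EM image pair
#'
#' Forward model of zero-loss energy-filtered imaging: electrons crossing a
#' vitreous ice layer of thickness `t` are inelastically scattered with mean
#' free path `lambda_inel`, so the zero-loss filtered intensity is
#' `I_zl = I_t * exp(-t / lambda_inel)` while the unfiltered image keeps all
#' electrons (`I_t = I0`). At zero noise the pair is exactly inverted by
#' [thickness_map()].
#'
#' @param field Thickness matrix in nm (>= 0).
#' @param lambda_inel Inelastic mean free path in nm (> 0); 322 nm is a
#'   literature value for vitreous ice at 300 kV.
#' @param I0 Incident intensity in counts (> 0).
#' @param noise_sd Additive Gaussian noise in counts (0 disables).
#' @param pixel_size_nm Pixel size of the EM raster in nm/px.
#' @param seed Seed for the noise draw.
#' @return An object of class `em_pair` with `unfiltered`, `filtered`,
#'   `lambda_inel` and `pixel_size_nm`.
#' @export
#' @examples
#' pr <- simulate_em_pair(matrix(56, 8, 8), noise_sd = 0)
#' pr$filtered[1, 1] / pr$unfiltered[1, 1] # exp(-56/322)
simulate_em_pair <- function(field, lambda_inel = 322, I0 = 1000,
                             noise_sd = 0, pixel_size_nm = 20, seed = 1L) {
  if (!is.matrix(field) || any(!is.finite(field)) || any(field < 0)) {
    stop("`field` must be a finite matrix of thickness >= 0", call. = FALSE)
  }
  stopifnot_scalar(lambda_inel, "lambda_inel", 0, strict = TRUE)
  stopifnot_scalar(I0, "I0", 0, strict = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  unf <- matrix(I0, nrow(field), ncol(field))
  fil <- I0 * exp(-field / lambda_inel)
  if (noise_sd > 0) {
    with_seed(seed, {
      unf <- unf + matrix(stats::rnorm(length(unf), 0, noise_sd), nrow(unf))
      fil <- fil + matrix(stats::rnorm(length(fil), 0, noise_sd), nrow(fil))
    })
  }
  structure(list(unfiltered = unf, filtered = fil,
                 lambda_inel = lambda_inel, pixel_size_nm = pixel_size_nm),
            class = "em_pair")
}

#' Simulate a low-magnification EM view of one grid square with foil holes
#'
#' Builds the total projected thickness of a grid square whose support foil
#' (adding `foil_nm` of equivalent material) carries a regular array of
#' circular holes, on top of a class-conditioned ice field, and images it
#' with [simulate_em_pair()]. In the filtered image the holes appear as
#' bright discs, which is what [detect_holes()] operates on.
#'
#' @param field Ice-thickness matrix in nm (e.g. from
#'   [sample_thickness_field()]); its raster spans the open square.
#' @param grid A [grid_spec()]; sets hole diameter and spacing.
#' @param square_um Side of the imaged square region in um.
#' @param foil_nm Equivalent thickness added by the foil outside holes.
#' @param ... Passed to [simulate_em_pair()].
#' @return The `em_pair`, with attributes `holes` (data.frame of complete
#'   hole centres/radii in px) and `hole_mask`.
#' @export
simulate_em_square <- function(field, grid = quantifoil_cu200_r2_1(),
                               square_um = 90, foil_nm = 40, ...) {
  n <- nrow(field)
  px_um <- square_um / n # um per pixel
  hp <- grid$hole_diameter + grid$hole_spacing
  xy <- (seq_len(n) - 0.5) * px_um
  hx <- outer(rep(1, n), xy) %% hp - hp / 2
  hy <- outer(xy, rep(1, n)) %% hp - hp / 2
  hole <- (hx^2 + hy^2) < (grid$hole_diameter / 2)^2
  total <- field + foil_nm * !hole
  pair <- simulate_em_pair(total, pixel_size_nm = px_um * 1000, ...)
  # Complete hole centres (truth for detector tests).
  centers_um <- seq(hp / 2, square_um, by = hp)
  rad_px <- grid$hole_diameter / 2 / px_um
  cen <- expand.grid(row = centers_um / px_um + 0.5,
                     col = centers_um / px_um + 0.5)
  keep <- cen$row - rad_px >= 1 & cen$row + rad_px <= n &
    cen$col - rad_px >= 1 & cen$col + rad_px <= n
  attr(pair, "holes") <- data.frame(row = cen$row[keep], col = cen$col[keep],
                                    radius = rad_px)
  attr(pair, "hole_mask") <- hole
  pair
}
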