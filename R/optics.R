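#' Three-wavelength illumination band set
#'
#' The screening microscope illuminates the grid through a triple-bandpass
#' filter, so each camera channel sees a narrow band around one centre
#' wavelength. Defaults follow a 433/517/613 nm tripleband filter; the
#' passband widths are not critical and default to 20 nm FWHM.
#'
#' @param centers Numeric length-3, band centre wavelengths in nm, strictly
#'   increasing (blue, green, red channel).
#' @param fwhm Full width at half maximum of each band in nm; scalar or
#'   length 3.
#' @return An object of class `wavelength_set`.
#' @export
#' @examples
#' wavelength_set()
wavelength_set <- function(centers = c(433, 517, 613), fwhm = 20) {
  if (length(centers) != 3L || any(!is.finite(centers)) || any(centers <= 0)) {
    stop("`centers` must be three positive finite wavelengths (nm)", call. = FALSE)
  }
  if (any(diff(centers) <= 0)) {
    stop("`centers` must be strictly increasing", call. = FALSE)
  }
  fwhm <- rep_len(fwhm, 3L)
  if (any(!is.finite(fwhm)) || any(fwhm <= 0)) {
    stop("`fwhm` must be positive and finite", call. = FALSE)
  }
  structure(list(centers = as.numeric(centers), fwhm = as.numeric(fwhm)),
            class = "wavelength_set")
}

#' Thin-film stack for a free-standing vitreous ice layer
#'
#' Describes the optical stack seen by the interferometer: a film of
#' amorphous ice (refractive index `n_film`, default 1.31) bounded by two
#' ambient media. The amplitude reflectances of the two interfaces, r1
#' (above/film) and r2 (film/below), follow from the Fresnel formula at
#' normal incidence. For the default free-standing film (vacuum/ice/vacuum)
#' r1 = -r2, so the film reflects nothing at zero thickness.
#'
#' @param n_film Refractive index of the film (amorphous ice ~ 1.31).
#' @param n_above,n_below Refractive indices of the bounding media.
#' @return An object of class `film_stack` with fields `r1` and `r2`.
#' @export
film_stack <- function(n_film = 1.31, n_above = 1.0, n_below = 1.0) {
  for (nm in c("n_film", "n_above", "n_below")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1) {
      stop(sprintf("`%s` must be a single finite index >= 1", nm), call. = FALSE)
    }
  }
  structure(list(
    n_film = n_film, n_above = n_above, n_below = n_below,
    r1 = fresnel_amplitude(n_above, n_film),
    r2 = fresnel_amplitude(n_film, n_below)
  ), class = "film_stack")
}

#' Fresnel amplitude reflectance at normal incidence
#'
#' @param n_incident,n_transmitted Refractive indices of the two media
#'   (each >= 1).
#' @return `(n_incident - n_transmitted) / (n_incident + n_transmitted)`,
#'   a value in (-1, 1).
#' @export
#' @examples
#' fresnel_amplitude(1.0, 1.31) # air -> ice, about -0.134
fresnel_amplitude <- function(n_incident, n_transmitted) {
  if (!is.numeric(n_incident) || !is.numeric(n_transmitted) ||
      any(!is.finite(n_incident)) || any(!is.finite(n_transmitted)) ||
      any(n_incident < 1) || any(n_transmitted < 1)) {
    stop("refractive indices must be finite and >= 1", call. = FALSE)
  }
  (n_incident - n_transmitted) / (n_incident + n_transmitted)
}

#' Two-beam thin-film reflectance
#'
#' First-order (two-beam) interference of the reflections from the top and
#' bottom film interfaces:
#' `R(t, lambda) = r1^2 + r2^2 + 2 r1 r2 cos(4 pi n t / lambda)`.
#' At the ~0.13 amplitude reflectance of an ice/air interface, multiple
#' internal reflections contribute below 1e-3 of the signal and are omitted.
#' R is periodic in thickness with period `lambda / (2 n)`; for a symmetric
#' stack (r1 = -r2) it vanishes at t = 0 and peaks at quarter-wave
#' thickness.
#'
#' @param t Film thickness in nm (vectorised, all >= 0).
#' @param lambda Wavelength in nm (> 0).
#' @param stack A [film_stack()].
#' @return Reflectance values in `[0, (|r1|+|r2|)^2]`.
#' @export
#' @examples
#' film_reflectance(40, 433, film_stack())
film_reflectance <- function(t, lambda, stack = film_stack()) {
  if (!inherits(stack, "film_stack")) stop("`stack` must be a film_stack", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("thickness `t` must be finite and >= 0", call. = FALSE)
  }
  stopifnot_scalar(lambda, "lambda", 0, strict = TRUE)
  r1 <- stack$r1; r2 <- stack$r2
  r1^2 + r2^2 + 2 * r1 * r2 * cos(4 * pi * stack$n_film * t / lambda)
}

# 5-point Gauss-Legendre nodes/weights on [-1, 1].
.gl5 <- list(
  x = c(-0.906179845938664, -0.538469310105683, 0,
        0.538469310105683, 0.906179845938664),
  w = c(0.236926885056189, 0.478628670499366, 0.568888888888889,
        0.478628670499366, 0.236926885056189)
)

#' Band-averaged film reflectance per camera channel
#'
#' Averages [film_reflectance()] over each filter passband with 5-point
#' Gauss-Legendre quadrature across the FWHM, which washes out fringes whose
#' period approaches the coherence length, as seen in real images of very
#' thick droplets.
#'
#' @param t Thickness vector in nm.
#' @param wavelengths A [wavelength_set()].
#' @param stack A [film_stack()].
#' @return A `length(t) x 3` matrix of channel reflectances.
#' @export
band_reflectance <- function(t, wavelengths = wavelength_set(),
                             stack = film_stack()) {
  if (!inherits(wavelengths, "wavelength_set")) {
    stop("`wavelengths` must be a wavelength_set", call. = FALSE)
  }
  out <- matrix(0, length(t), 3L)
  for (ch in 1:3) {
    lo <- wavelengths$centers[ch] - wavelengths$fwhm[ch] / 2
    hi <- wavelengths$centers[ch] + wavelengths$fwhm[ch] / 2
    mid <- (lo + hi) / 2; half <- (hi - lo) / 2
    acc <- 0
    for (q in 1:5) {
      acc <- acc + .gl5$w[q] * film_reflectance(t, mid + half * .gl5$x[q], stack)
    }
    out[, ch] <- acc / 2 # Legendre weights sum to 2
  }
  out
}
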