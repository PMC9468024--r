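#' EM support-grid geometry
#'
#' Geometry of a standard square-mesh EM grid as seen by the optical
#' screening microscope. All lengths are in micrometres. A mesh of pitch
#' `p` with bar width `b` leaves open (filmed) squares of side `p - b`
#' separated by metal bars; the support foil inside each square carries a
#' regular array of circular holes (e.g. "R2/1" = 2 um holes with 1 um
#' edge-to-edge spacing).
#'
#' @param pitch Mesh pitch in um (centre-to-centre bar distance).
#' @param bar_width Grid-bar width in um (< pitch).
#' @param hole_diameter Foil-hole diameter in um.
#' @param hole_spacing Edge-to-edge hole spacing in um.
#' @param bar_reflectance Displayed reflectance of the metal bars in [0, 1].
#' @param name Free-text label of the grid type.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' quantifoil_cu200_r2_1()
grid_spec <- function(pitch = 125, bar_width = 35, hole_diameter = 2,
                      hole_spacing = 1, bar_reflectance = 0.7,
                      name = "generic") {
  stopifnot_scalar(pitch, "pitch", 0, strict = TRUE)
  stopifnot_scalar(bar_width, "bar_width", 0, strict = TRUE)
  stopifnot_scalar(hole_diameter, "hole_diameter", 0, strict = TRUE)
  stopifnot_scalar(hole_spacing, "hole_spacing", 0)
  if (bar_width >= pitch) stop("`bar_width` must be smaller than `pitch`", call. = FALSE)
  if (bar_reflectance < 0 || bar_reflectance > 1) {
    stop("`bar_reflectance` must be in [0, 1]", call. = FALSE)
  }
  structure(list(pitch = pitch, bar_width = bar_width,
                 hole_diameter = hole_diameter, hole_spacing = hole_spacing,
                 bar_reflectance = bar_reflectance, name = name),
            class = "grid_spec")
}

#' @describeIn grid_spec Quantifoil Cu 200 mesh, R2/1 holey carbon.
#' @export
quantifoil_cu200_r2_1 <- function() {
  grid_spec(pitch = 125, bar_width = 35, hole_diameter = 2, hole_spacing = 1,
            bar_reflectance = 0.7, name = "Quantifoil Cu 200 R2/1")
}

#' @describeIn grid_spec UltrAuFoil Au 300 mesh, R1.2/1.3 holey gold foil.
#' @export
ultraaufoil_au300_r12_13 <- function() {
  grid_spec(pitch = 85, bar_width = 25, hole_diameter = 1.2, hole_spacing = 1.3,
            bar_reflectance = 0.75, name = "UltrAuFoil Au 300 R1.2/1.3")
}

#' Pixel size of the screening camera at a given objective magnification
#'
#' Assumes a 6.45 um camera pixel behind a 5x, 10x or 20x dry objective,
#' the three magnifications used for grid screening.
#'
#' @param magnification One of 5, 10, 20.
#' @return Pixel size in um/px.
#' @export
pixel_size_um <- function(magnification) {
  if (!magnification %in% c(5, 10, 20)) {
    stop("`magnification` must be 5, 10 or 20", call. = FALSE)
  }
  6.45 / magnification
}

# Default raster side (px) per magnification: large enough to hold at least
# one complete grid square of the 200-mesh geometry at any rotation.
default_image_size <- function(magnification) {
  switch(as.character(magnification), "5" = 512L, "10" = 512L, "20" = 768L)
}

# Hole-texture blur (um) per magnification; the foil holes are close to the
# optical resolution limit and appear strongly low-pass filtered.
hole_blur_um <- function(magnification) {
  switch(as.character(magnification), "5" = 0.9, "10" = 0.55, "20" = 0.35)
}
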