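#' The five ice-quality classes
#'
#' Grid squares are graded into five classes: 'bad' (0, defects such as
#' holes, scratches or dust), 'too thin' (1), 'optimal' (2), 'thicker' (3)
#' and 'too thick' (4). The display palette maps 0 to red, 1 to white, 2 to
#' green, 3 to bright green and 4 to orange.
#'
#' @return A data.frame with columns `class`, `name`, `color` (hex) and
#'   `r`, `g`, `b` in [0, 1].
#' @export
#' @examples
#' ice_classes()
ice_classes <- function() {
  data.frame(
    class = 0:4,
    name = c("bad", "too thin", "optimal", "thicker", "too thick"),
    color = c("#E02020", "#FFFFFF", "#00CC00", "#8CFF4D", "#FF9A00"),
    r = c(0.88, 1.00, 0.00, 0.55, 1.00),
    g = c(0.13, 1.00, 0.80, 1.00, 0.60),
    b = c(0.13, 1.00, 0.00, 0.30, 0.00),
    stringsAsFactors = FALSE
  )
}

#' Class-conditioned ice-thickness model
#'
#' Defines, per quality class, the distribution from which a grid square's
#' mean ice thickness is drawn and the spatial structure of the thickness
#' field. Default bins are anchored to EM-validated per-square means:
#' class 1 in 6-20 nm, class 2 in 20-50 nm centred near 40 nm, class 3 in
#' 50-70 nm centred near 56 nm, class 4 above 70 nm with a central sample
#' droplet peaking near 0.5 um (hence the circular periodic fringe pattern
#' of 'too thick' squares). Class 0 reuses a class 1-3 field and adds one
#' or two defects from the catalogue (punched hole, scratch, dust).
#'
#' @param bins List of 4 length-2 numeric vectors, the admissible per-square
#'   mean-thickness bin (nm) for classes 1-4.
#' @param spread Within-square thickness standard deviation (nm) per class
#'   1-4.
#' @param droplet_peak Range (nm) of the class-4 droplet peak height.
#' @param droplet_sigma Range of the droplet Gaussian radius, as a fraction
#'   of the square side.
#' @param puddle_height Height (nm) of the class-3 centre puddle.
#' @param puddle_sigma Radius of the class-3 puddle (fraction of side).
#' @param defect_types Defect catalogue for class 0.
#' @param defect_weights Sampling weights of `defect_types`.
#' @return An object of class `ice_class_model`.
#' @export
class_model <- function(bins = list(c(6, 20), c(20, 50), c(50, 70), c(70, 100)),
                        spread = c(1.5, 3, 4, 5),
                        droplet_peak = c(460, 540),
                        droplet_sigma = c(0.05, 0.08),
                        puddle_height = 18,
                        puddle_sigma = 0.25,
                        defect_types = c("hole", "scratch", "dust"),
                        defect_weights = c(0.5, 0.3, 0.2)) {
  if (length(bins) != 4L || any(vapply(bins, length, 1L) != 2L)) {
    stop("`bins` must be a list of four (lo, hi) pairs", call. = FALSE)
  }
  mids <- vapply(bins, mean, 0)
  if (any(diff(mids) <= 0)) {
    stop("class mean-thickness bins must increase from class 1 to class 4",
         call. = FALSE)
  }
  if (min(droplet_peak) < 400) {
    stop("class-4 droplet peak must be >= 400 nm", call. = FALSE)
  }
  if (length(spread) != 4L || any(spread < 0)) {
    stop("`spread` must be four non-negative values", call. = FALSE)
  }
  structure(list(bins = bins, spread = spread, droplet_peak = droplet_peak,
                 droplet_sigma = droplet_sigma, puddle_height = puddle_height,
                 puddle_sigma = puddle_sigma, defect_types = defect_types,
                 defect_weights = defect_weights),
            class = "ice_class_model")
}

# Truncated-normal draw by rejection (narrow use; bounds well within 3 sd).
rtnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# Draw the parametric description of one square's thickness field using the
# current RNG stream. The field is a sum of smooth low-order harmonics plus
# an optional centre bump (class 3) or droplet (class 4); the whole field is
# shifted afterwards so that its mean over the unit square equals the drawn
# target mean.
draw_square_params <- function(label, model) {
  stopifnot(label %in% 0:4)
  base <- label
  defects <- list()
  if (label == 0L) {
    base <- sample(1:3, 1L)
    n_def <- sample(1:2, 1L)
    for (i in seq_len(n_def)) {
      type <- sample(model$defect_types, 1L, prob = model$defect_weights)
      defects[[i]] <- switch(type,
        hole = list(type = "hole",
                    a0 = stats::runif(1, 0.25, 0.75), b0 = stats::runif(1, 0.25, 0.75),
                    rad = stats::runif(1, 0.12, 0.25)),
        scratch = list(type = "scratch",
                       a0 = stats::runif(1, 0.2, 0.8), b0 = stats::runif(1, 0.2, 0.8),
                       psi = stats::runif(1, 0, pi),
                       halfwidth = stats::runif(1, 0.025, 0.05)),
        dust = list(type = "dust",
                    a0 = stats::runif(1, 0.15, 0.85), b0 = stats::runif(1, 0.15, 0.85),
                    rad = stats::runif(1, 0.08, 0.16),
                    shade = stats::runif(1, 0.8, 1.2))
      )
    }
  }
  bin <- model$bins[[base]]
  m_target <- switch(base,
    stats::runif(1, bin[1] + 2, bin[2] - 2),                      # class 1
    rtnorm1(40, 5, bin[1] + 5, bin[2] - 2),                       # class 2
    rtnorm1(56, 3.5, bin[1] + 1, bin[2] - 2),                     # class 3
    stats::runif(1, bin[1] + 4, bin[2] - 12)                      # class 4
  )
  spread <- model$spread[base]
  K <- 3L
  amp_raw <- abs(stats::rnorm(K))
  scale <- if (sum(amp_raw^2) > 0) sqrt(2 * spread^2 / sum(amp_raw^2)) else 0
  p <- list(
    label = label, base = base, m_target = m_target, spread = spread,
    amp = amp_raw * scale,
    fa = stats::runif(K, 0.5, 2.2), fb = stats::runif(K, 0.5, 2.2),
    ph = stats::runif(K, 0, 2 * pi),
    bump = NULL, droplet = NULL, defects = defects
  )
  if (base == 3L) {
    p$bump <- list(height = model$puddle_height, sigma = model$puddle_sigma,
                   a0 = stats::runif(1, 0.42, 0.58), b0 = stats::runif(1, 0.42, 0.58))
  }
  if (base == 4L) {
    p$droplet <- list(peak = stats::runif(1, model$droplet_peak[1], model$droplet_peak[2]),
                      sigma = stats::runif(1, model$droplet_sigma[1], model$droplet_sigma[2]),
                      a0 = stats::runif(1, 0.45, 0.55), b0 = stats::runif(1, 0.45, 0.55))
  }
  # Mean shift on a reference raster so the realised square mean hits target.
  g <- seq(0.5 / 64, 1 - 0.5 / 64, length.out = 64)
  ref <- eval_square_field(outer(rep(1, 64), g), outer(g, rep(1, 64)), p,
                           shifted = FALSE)
  p$shift <- m_target - mean(ref)
  p
}

# Evaluate a square's thickness field at normalised in-square coordinates
# (a across columns, b across rows), both in [0, 1].
eval_square_field <- function(a, b, params, shifted = TRUE) {
  t <- 0
  for (k in seq_along(params$amp)) {
    t <- t + params$amp[k] *
      cos(2 * pi * (params$fa[k] * a + params$fb[k] * b) + params$ph[k])
  }
  if (!is.null(params$bump)) {
    bb <- params$bump
    t <- t + bb$height * exp(-((a - bb$a0)^2 + (b - bb$b0)^2) / (2 * bb$sigma^2))
  }
  if (!is.null(params$droplet)) {
    dd <- params$droplet
    t <- t + dd$peak * exp(-((a - dd$a0)^2 + (b - dd$b0)^2) / (2 * dd$sigma^2))
  }
  if (shifted) {
    # physical field: apply the mean-matching shift and the 0.5 nm floor
    t <- pmax(t + params$shift, 0.5)
  }
  t
}

#' Sample a class-conditioned ice-thickness field for one grid square
#'
#' Draws the random parameters of a single square's thickness field for the
#' requested quality class and evaluates them on a square raster spanning
#' the open (filmed) area. Classes 1 and 2 give a near-uniform field with
#' smooth low-order variation, class 3 adds a centre-weighted thicker
#' puddle, class 4 a central droplet reaching several hundred nm, and class
#' 0 reuses a class 1-3 field (its defects only affect rendering). The
#' per-square mean is constrained to the class's configured bin, and the
#' same seed always reproduces the same field.
#'
#' @param label Integer class 0-4.
#' @param grid A [grid_spec()] (carried for provenance; the field is
#'   expressed on the unit square).
#' @param model An [class_model()].
#' @param seed Integer seed.
#' @param n_px Raster side in pixels.
#' @return A `n_px x n_px` matrix of thickness in nm with attributes
#'   `params` and `label`.
#' @export
#' @examples
#' f <- sample_thickness_field(2, seed = 7)
#' mean(f) # within the class-2 bin
sample_thickness_field <- function(label, grid = quantifoil_cu200_r2_1(),
                                   model = class_model(), seed = 1L,
                                   n_px = 128L) {
  if (!label %in% 0:4) stop("`label` must be an integer class 0-4", call. = FALSE)
  params <- with_seed(seed, draw_square_params(label, model))
  g <- seq(0.5 / n_px, 1 - 0.5 / n_px, length.out = n_px)
  a <- outer(rep(1, n_px), g) # column coordinate
  b <- outer(g, rep(1, n_px)) # row coordinate
  f <- eval_square_field(a, b, params)
  attr(f, "params") <- params
  attr(f, "label") <- label
  f
}
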