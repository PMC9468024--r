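# Display constants for rendering. The raw two-beam reflectance of an
# ice/air film peaks at (|r1|+|r2|)^2 (~0.07); the camera gain is chosen so
# that this peak maps close to full scale, on top of a uniform reflectance
# offset contributed by the support foil (no structural carbon contrast is
# modelled beyond this offset, which dips slightly inside the foil holes).
.render_const <- list(
  gain_frac = 0.85,   # fraction of full scale at the interference maximum
  foil_offset = 0.12, # uniform foil reflectance offset
  hole_dip = 0.05,    # offset reduction inside a foil hole
  defect_colors = list(
    hole = c(0.015, 0.015, 0.015),
    scratch = c(0.03, 0.03, 0.03),
    dust = c(0.07, 0.05, 0.03)
  )
)

#' Render a synthetic interferogram with ground truth
#'
#' Turns an [build_scene()] description into the RGB image a three-band
#' interferometric microscope would record: each channel is the
#' band-averaged two-beam reflectance of the local ice film, the metal bars
#' are rendered at the grid's bar reflectance, defects override the film
#' colour, and additive Gaussian noise is applied per channel. The exact
#' tile/background mask and per-square labels are returned alongside.
#'
#' @param scene An `interferogram_scene`.
#' @param wavelengths A [wavelength_set()].
#' @param noise_sd Additive Gaussian noise standard deviation on the [0, 1]
#'   reflectance scale (>= 0).
#' @param stack A [film_stack()].
#' @param seed Seed for the noise draw; rendering is bit-reproducible for a
#'   fixed scene and seed.
#' @return An object of class `interferogram`: a list with `image`
#'   (`H x W x 3` array in [0, 1]), `tile_mask` (`H x W` 0/1 matrix, 1 =
#'   grid square), `squares` (data.frame with 0-based half-open bounding
#'   boxes `row0, col0, row1, col1`, centres, class labels, mean thickness
#'   and a `complete` flag), plus `pixel_size`, `magnification` and `angle`.
#' @export
#' @examples
#' sc <- build_scene(magnification = 5, labels = 2, seed = 1)
#' ig <- render_interferogram(sc, noise_sd = 0, seed = 1)
render_interferogram <- function(scene, wavelengths = wavelength_set(),
                                 noise_sd = 0.02, stack = film_stack(),
                                 seed = 1L) {
  if (!inherits(scene, "interferogram_scene")) {
    stop("`scene` must be an interferogram_scene", call. = FALSE)
  }
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  h <- scene$dim[1L]; w <- scene$dim[2L]
  g <- scene$grid
  p <- g$pitch; bw <- g$bar_width; open_w <- p - bw

  co <- scene_grid_coords(scene)
  uu <- co$u %% p; vv <- co$v %% p
  bar <- uu < bw / 2 | uu > p - bw / 2 | vv < bw / 2 | vv > p - bw / 2
  open <- !bar
  iu <- floor(co$u / p); iv <- floor(co$v / p)

  # Lookup from cell index to the scene's parameter table.
  iu0 <- min(scene$cells$iu); iv0 <- min(scene$cells$iv)
  n_iu <- max(scene$cells$iu) - iu0 + 1L
  cell_row <- rep(NA_integer_, n_iu * (max(scene$cells$iv) - iv0 + 1L))
  cell_row[(scene$cells$iu - iu0) + n_iu * (scene$cells$iv - iv0) + 1L] <-
    seq_len(nrow(scene$cells))
  pix_cell <- rep(NA_integer_, h * w)
  pix_cell[open] <- cell_row[(iu[open] - iu0) + n_iu * (iv[open] - iv0) + 1L]

  t_nm <- numeric(h * w)
  chan <- matrix(0, h * w, 3L)
  defect_idx <- integer(0); defect_col <- matrix(0, 0, 3L)
  sq_rows <- list(); sq_masks <- list()

  present <- sort(unique(pix_cell[open]))
  for (ci in present) {
    sel <- which(!is.na(pix_cell) & pix_cell == ci)
    prm <- scene$params[[ci]]
    a <- (uu[sel] - bw / 2) / open_w
    b <- (vv[sel] - bw / 2) / open_w
    t_nm[sel] <- eval_square_field(a, b, prm)
    for (d in prm$defects) {
      member <- switch(d$type,
        hole = , dust = ((a - d$a0)^2 + (b - d$b0)^2) < d$rad^2,
        scratch = abs(sin(d$psi) * (a - d$a0) - cos(d$psi) * (b - d$b0)) <
          d$halfwidth
      )
      if (any(member)) {
        col <- .render_const$defect_colors[[d$type]]
        if (d$type == "dust") col <- col * d$shade
        defect_idx <- c(defect_idx, sel[member])
        defect_col <- rbind(defect_col,
                            matrix(col, sum(member), 3L, byrow = TRUE))
      }
    }
    # Per-square ground truth record.
    r <- ((sel - 1L) %% h) + 1L
    cc <- ((sel - 1L) %/% h) + 1L
    sub <- matrix(0, max(r) - min(r) + 1L, max(cc) - min(cc) + 1L)
    sub[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- 1
    sq_masks[[length(sq_rows) + 1L]] <- sub
    sq_rows[[length(sq_rows) + 1L]] <- data.frame(
      iu = scene$cells$iu[ci], iv = scene$cells$iv[ci],
      class = scene$cells$label[ci],
      row0 = min(r) - 1L, col0 = min(cc) - 1L, row1 = max(r), col1 = max(cc),
      center_row = mean(r) - 0.5, center_col = mean(cc) - 0.5,
      area_px = length(sel),
      mean_thickness = mean(t_nm[sel]),
      complete = square_is_complete(scene, scene$cells$iu[ci], scene$cells$iv[ci])
    )
  }

  # Film colour: band-averaged reflectance plus the foil offset.
  r1 <- stack$r1; r2 <- stack$r2
  gain <- .render_const$gain_frac / (abs(r1) + abs(r2))^2
  open_i <- which(open)
  rb <- band_reflectance(t_nm[open_i], wavelengths, stack)
  offset <- .render_const$foil_offset
  if (scene$render_holes) {
    hp <- g$hole_diameter + g$hole_spacing
    hu <- co$u[open_i] %% hp - hp / 2
    hv <- co$v[open_i] %% hp - hp / 2
    dist <- sqrt(hu^2 + hv^2)
    cov <- stats::plogis((g$hole_diameter / 2 - dist) /
                           hole_blur_um(scene$magnification))
    offset <- offset - .render_const$hole_dip * cov
  }
  for (ch in 1:3) chan[open_i, ch] <- gain * rb[, ch] + offset
  chan[bar, ] <- g$bar_reflectance
  if (length(defect_idx)) chan[defect_idx, ] <- defect_col

  img <- with_seed(seed, {
    noisy <- chan + if (noise_sd > 0) {
      matrix(stats::rnorm(length(chan), 0, noise_sd), nrow(chan), 3L)
    } else 0
    array(clamp01(noisy), dim = c(h, w, 3L))
  })

  squares <- do.call(rbind, sq_rows)
  ord <- order(squares$row0, squares$col0)
  squares <- squares[ord, , drop = FALSE]
  sq_masks <- sq_masks[ord]
  squares$id <- seq_len(nrow(squares))
  rownames(squares) <- NULL

  structure(list(
    image = img,
    tile_mask = matrix(as.numeric(open), h, w),
    squares = squares, square_masks = sq_masks,
    scene = scene,
    pixel_size = scene$pixel_size, magnification = scene$magnification,
    angle = scene$angle, noise_sd = noise_sd, seed = seed
  ), class = "interferogram")
}

# A square is complete when all four corners of its open area fall inside
# the raster.
square_is_complete <- function(scene, iu, iv, margin = 0.5) {
  g <- scene$grid
  us <- iu * g$pitch + c(g$bar_width / 2, g$pitch - g$bar_width / 2)
  vs <- iv * g$pitch + c(g$bar_width / 2, g$pitch - g$bar_width / 2)
  th <- scene$angle * pi / 180
  h <- scene$dim[1L]; w <- scene$dim[2L]
  for (u in us) for (v in vs) {
    U <- (u - scene$offset[1]) / scene$pixel_size
    V <- (v - scene$offset[2]) / scene$pixel_size
    x <- cos(th) * U - sin(th) * V + w / 2
    y <- sin(th) * U + cos(th) * V + h / 2
    if (x < margin || x > w - margin || y < margin || y > h - margin) {
      return(FALSE)
    }
  }
  TRUE
}

# Image-frame pixel positions (row, col, 1-based centres) of the four
# corners of a square's open area.
square_corners_px <- function(scene, iu, iv) {
  g <- scene$grid
  us <- iu * g$pitch + c(g$bar_width / 2, g$pitch - g$bar_width / 2)
  vs <- iv * g$pitch + c(g$bar_width / 2, g$pitch - g$bar_width / 2)
  th <- scene$angle * pi / 180
  h <- scene$dim[1L]; w <- scene$dim[2L]
  out <- matrix(0, 4L, 2L, dimnames = list(NULL, c("row", "col")))
  i <- 1L
  for (u in us) for (v in vs) {
    U <- (u - scene$offset[1]) / scene$pixel_size
    V <- (v - scene$offset[2]) / scene$pixel_size
    out[i, ] <- c(sin(th) * U + cos(th) * V + h / 2,
                  cos(th) * U - sin(th) * V + w / 2)
    i <- i + 1L
  }
  out
}

# Coerce pipeline inputs: accept an `interferogram`, an [H, W, 3] array or
# an [H, W] matrix and return an [H, W, 3] array.
as_image_array <- function(image) {
  if (inherits(image, "interferogram")) image <- image$image
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("`image` must be an interferogram, H x W x 3 array or H x W matrix",
         call. = FALSE)
  }
  image
}
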