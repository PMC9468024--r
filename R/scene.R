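#' Build a synthetic interferometric scene of an EM grid
#'
#' Lays out a square mesh at a given magnification and in-plane rotation,
#' assigns every grid square a quality class (drawn from `class_mix` or
#' forced via `labels`) and draws the parametric thickness field and defect
#' set of each square. The scene is a complete, seeded ground-truth
#' description; [render_interferogram()] turns it into an RGB image plus
#' masks and per-square labels.
#'
#' Raster convention: origin at the top-left pixel, row-major storage,
#' row index increasing downwards. `angle` is the in-plane grid rotation in
#' degrees (counter-clockwise positive in these pixel coordinates), folded
#' by the mesh's 90-degree symmetry into [-45, 45).
#'
#' @param grid A [grid_spec()].
#' @param magnification Objective magnification, 5, 10 or 20.
#' @param dim Raster size `c(nrow, ncol)` in px; default depends on the
#'   magnification.
#' @param angle Grid rotation in degrees; `NULL` draws uniformly from
#'   `angle_range`.
#' @param angle_range Range the rotation is drawn from when `angle` is NULL.
#' @param class_mix Length-5 class proportions (classes 0-4) for random
#'   square labels; must sum to 1.
#' @param labels Optional single class 0-4 forced on every square.
#' @param model An [class_model()].
#' @param render_holes Render the barely-resolved foil-hole texture?
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @return An object of class `interferogram_scene`.
#' @export
#' @examples
#' sc <- build_scene(magnification = 5, labels = 2, seed = 1)
build_scene <- function(grid = quantifoil_cu200_r2_1(), magnification = 5,
                        dim = NULL, angle = NULL, angle_range = c(-40, 40),
                        class_mix = c(0.1, 0.2, 0.3, 0.25, 0.15),
                        labels = NULL, model = class_model(),
                        render_holes = TRUE, seed = 1L) {
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec", call. = FALSE)
  ps <- pixel_size_um(magnification)
  if (is.null(dim)) dim <- rep(default_image_size(magnification), 2L)
  dim <- as.integer(dim)
  if (length(dim) != 2L || any(dim < 8L)) stop("`dim` must be two sizes >= 8", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-6 || length(class_mix) != 5L || any(class_mix < 0)) {
    stop("`class_mix` must be five non-negative proportions summing to 1", call. = FALSE)
  }
  if (!is.null(labels) && !all(labels %in% 0:4)) {
    stop("`labels` must be classes in 0-4", call. = FALSE)
  }

  with_seed(seed, {
    if (is.null(angle)) angle <- stats::runif(1, angle_range[1], angle_range[2])
    angle <- ((angle + 45) %% 90) - 45
    pitch_px <- grid$pitch / ps
    th <- angle * pi / 180
    if (pitch_px * (abs(cos(th)) + abs(sin(th))) > min(dim)) {
      stop("raster too small to hold one full grid square at this rotation",
           call. = FALSE)
    }
    offset <- stats::runif(2, 0, grid$pitch)

    # Cell index range covering the raster (grid frame, um).
    cx <- dim[2L] / 2; cy <- dim[1L] / 2
    corners_x <- c(0, dim[2L], 0, dim[2L]) - cx
    corners_y <- c(0, 0, dim[1L], dim[1L]) - cy
    u <- (cos(th) * corners_x + sin(th) * corners_y) * ps + offset[1]
    v <- (-sin(th) * corners_x + cos(th) * corners_y) * ps + offset[2]
    iu_range <- floor(range(u) / grid$pitch) + c(-1L, 1L)
    iv_range <- floor(range(v) / grid$pitch) + c(-1L, 1L)
    cells <- expand.grid(iu = seq(iu_range[1], iu_range[2]),
                         iv = seq(iv_range[1], iv_range[2]))
    n_cells <- nrow(cells)
    cell_labels <- if (is.null(labels)) {
      sample(0:4, n_cells, replace = TRUE, prob = class_mix)
    } else rep_len(labels, n_cells)
    params <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      params[[i]] <- draw_square_params(cell_labels[i], model)
    }

    structure(list(
      grid = grid, magnification = magnification, pixel_size = ps,
      dim = dim, angle = angle, offset = offset,
      cells = cbind(cells, label = cell_labels),
      params = params, model = model, render_holes = render_holes,
      seed = seed
    ), class = "interferogram_scene")
  })
}

# Map pixel centres to grid-frame coordinates in um. Returns list(u, v) of
# length nrow*ncol, column-major over the [H, W] raster.
scene_grid_coords <- function(scene) {
  h <- scene$dim[1L]; w <- scene$dim[2L]
  th <- scene$angle * pi / 180
  x <- rep(seq_len(w) - 0.5 - w / 2, each = h)
  y <- rep(seq_len(h) - 0.5 - h / 2, times = w)
  list(
    u = (cos(th) * x + sin(th) * y) * scene$pixel_size + scene$offset[1],
    v = (-sin(th) * x + cos(th) * y) * scene$pixel_size + scene$offset[2]
  )
}
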