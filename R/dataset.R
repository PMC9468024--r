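#' Generate a labelled synthetic screening dataset on disk
#'
#' Renders `n_images` seeded synthetic interferograms with random grid
#' rotations and class mixes and writes the standard training layout:
#' `images/` (8-bit RGB PNG), `masks/` (tile/background label PNG),
#' `manifest.json` (per-image angle plus every square's bounding box, class
#' and mean thickness) and `config.yaml` (the generation parameters). Two
#' calls with the same arguments produce identical manifests; with
#' `dir = NULL` nothing is written and the rendered images are returned
#' in memory.
#'
#' @param n_images Number of images (>= 1).
#' @param class_mix Length-5 class proportions (classes 0-4), summing to 1.
#' @param magnification 5, 10 or 20, or a vector cycled over images.
#' @param grid A [grid_spec()].
#' @param model An [class_model()].
#' @param noise_sd Rendering noise.
#' @param angle_range Grid-rotation range in degrees.
#' @param dim Optional raster size override.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed), or `NULL` for
#'   in-memory use.
#' @return Invisibly, a list with `manifest` and (if `dir` is NULL)
#'   `images` (the `interferogram` objects).
#' @export
make_dataset <- function(n_images, class_mix = c(0.1, 0.2, 0.3, 0.25, 0.15),
                         magnification = 5, grid = quantifoil_cu200_r2_1(),
                         model = class_model(), noise_sd = 0.02,
                         angle_range = c(-40, 40), dim = NULL, seed = 1L,
                         dir = NULL) {
  if (n_images < 1) stop("`n_images` must be >= 1", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-6) {
    stop("`class_mix` must sum to 1", call. = FALSE)
  }
  mags <- rep_len(magnification, n_images)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n_images))
  if (!is.null(dir)) {
    for (d in file.path(dir, c("images", "masks"))) {
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    }
    if (!dir.exists(dir)) stop("cannot create output directory", call. = FALSE)
  }
  images <- if (is.null(dir)) vector("list", n_images) else NULL
  entries <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- build_scene(grid = grid, magnification = mags[i], dim = dim,
                      angle_range = angle_range, class_mix = class_mix,
                      model = model, seed = seeds[2L * i - 1L])
    ig <- render_interferogram(sc, noise_sd = noise_sd, seed = seeds[2L * i])
    name <- sprintf("img_%04d", i)
    sq <- ig$squares
    entry <- list(
      file = file.path("images", paste0(name, ".png")),
      mask_file = file.path("masks", paste0(name, "_mask.png")),
      magnification = mags[i], angle = ig$angle, noise_sd = noise_sd,
      squares = sq[, c("id", "class", "row0", "col0", "row1", "col1",
                       "center_row", "center_col", "area_px",
                       "mean_thickness", "complete")]
    )
    if (!is.null(dir)) {
      png::writePNG(ig$image, file.path(dir, entry$file))
      png::writePNG(ig$tile_mask, file.path(dir, entry$mask_file))
    } else {
      images[[i]] <- ig
    }
    entries[[i]] <- entry
  }
  manifest <- list(generator = "icescreen", seed = seed, n_images = n_images,
                   class_mix = class_mix, images = entries)
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 8, dataframe = "rows")
    yaml::write_yaml(list(n_images = n_images, class_mix = class_mix,
                          magnification = magnification, noise_sd = noise_sd,
                          angle_range = angle_range, seed = seed,
                          grid = grid$name),
                     file.path(dir, "config.yaml"))
  }
  invisible(list(manifest = manifest, images = images))
}

#' Ground-truth tile detections of a rendered interferogram
#'
#' Converts the generator's per-square truth into the same detection
#' objects [postprocess_mask()] produces, for training and evaluation
#' against known labels.
#'
#' @param ig An `interferogram` from [render_interferogram()].
#' @param complete_only Keep only squares fully inside the raster?
#' @return List of `tile_detection` objects; each carries a `class`
#'   attribute with the true label.
#' @export
truth_detections <- function(ig, complete_only = TRUE) {
  out <- list()
  for (i in seq_len(nrow(ig$squares))) {
    s <- ig$squares[i, ]
    if (complete_only && !s$complete) next
    det <- structure(list(
      id = s$id,
      bbox = c(row0 = s$row0, col0 = s$col0, row1 = s$row1, col1 = s$col1),
      mask = ig$square_masks[[i]],
      area = s$area_px,
      aspect = max(s$row1 - s$row0, s$col1 - s$col0) /
        min(s$row1 - s$row0, s$col1 - s$col0),
      touches_border = !s$complete
    ), class = "tile_detection")
    attr(det, "class_label") <- s$class
    out[[length(out) + 1L]] <- det
  }
  out
}

#' Generate a labelled tile-crop corpus for classifier training
#'
#' Streams seeded synthetic images through the same path the analysis
#' pipeline uses: each rendered image is rotated to axis alignment, the
#' (ground-truth) square corners are mapped into the rotated frame, and a
#' fixed-size crop is extracted per complete square. Returns crop features
#' and true labels without retaining the images, so arbitrarily large
#' corpora fit in memory.
#'
#' @param n_images Number of source images.
#' @param class_mix Class proportions for the square labels.
#' @param magnification Magnification(s), cycled over images.
#' @param crop_size Crop side in px.
#' @param seed Integer seed.
#' @param noise_sd Rendering noise.
#' @param model,grid Generator configuration.
#' @param return_crops Also keep the crop arrays (memory permitting)?
#' @return A list with `features` (matrix), `labels` (integer vector) and
#'   optionally `crops`.
#' @export
make_tile_corpus <- function(n_images, class_mix = rep(0.2, 5),
                             magnification = 5, crop_size = 128L, seed = 1L,
                             noise_sd = 0.02, model = class_model(),
                             grid = quantifoil_cu200_r2_1(),
                             return_crops = FALSE) {
  mags <- rep_len(magnification, n_images)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n_images))
  feats <- list(); labs <- list(); crops_all <- list()
  for (i in seq_len(n_images)) {
    sc <- build_scene(grid = grid, magnification = mags[i],
                      class_mix = class_mix, model = model,
                      seed = seeds[2L * i - 1L])
    ig <- render_interferogram(sc, noise_sd = noise_sd, seed = seeds[2L * i])
    rot <- rotate_to_axis(ig, ig$angle)
    rinfo <- attr(rot, "rotation")
    sq <- ig$squares[ig$squares$complete, , drop = FALSE]
    if (!nrow(sq)) next
    dets <- list()
    for (j in seq_len(nrow(sq))) {
      corners <- map_points_to_rotated(
        square_corners_px(ig$scene, sq$iu[j], sq$iv[j]), rinfo)
      r0 <- max(1L, ceiling(min(corners[, 1]))); r1 <- floor(max(corners[, 1]))
      c0 <- max(1L, ceiling(min(corners[, 2]))); c1 <- floor(max(corners[, 2]))
      dets[[j]] <- structure(list(
        id = sq$id[j],
        bbox = c(row0 = r0 - 1L, col0 = c0 - 1L, row1 = r1, col1 = c1),
        mask = matrix(1, r1 - r0 + 1L, c1 - c0 + 1L),
        area = (r1 - r0 + 1L) * (c1 - c0 + 1L), aspect = 1,
        touches_border = FALSE
      ), class = "tile_detection")
    }
    cr <- extract_tile_crops(rot, dets, size = crop_size)
    if (!length(cr$crops)) next
    feats[[length(feats) + 1L]] <-
      t(vapply(cr$crops, tile_features, tile_features(cr$crops[[1L]])))
    labs[[length(labs) + 1L]] <- sq$class[match(cr$ids, sq$id)]
    if (return_crops) crops_all <- c(crops_all, cr$crops)
  }
  out <- list(features = do.call(rbind, feats), labels = unlist(labs))
  if (return_crops) out$crops <- crops_all
  out
}
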