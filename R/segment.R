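#' Segment grid squares (tiles) from an interferogram
#'
#' Two-class segmentation: tiles (the filmed grid squares) versus
#' background (the metal bars). The default, model-free path exploits the
#' appearance of the bars under three-band illumination: they are bright
#' and colourless (near-zero channel spread), whereas the ice film is
#' either dark or strongly coloured. Bar-like pixels are found by a
#' saturation/brightness rule, the bar mask is morphologically closed to
#' seal noise gaps, and the tile mask is its complement. With a model from
#' [train_segmenter()] a learned pixel classifier is used instead. Both
#' paths are deterministic for fixed inputs/weights.
#'
#' @param image An `interferogram`, `H x W x 3` array or grayscale matrix.
#' @param model Optional segmentation model from [train_segmenter()];
#'   `NULL` selects the classical path.
#' @param sat_thr Channel-spread threshold below which a pixel may be bar.
#' @param bright_tol Brightness half-window around the estimated bar level.
#' @param min_bar_frac Minimum fraction of bar-like pixels required to
#'   accept that a grid is present; below it an empty mask is returned.
#' @return A 0/1 tile mask matrix (1 = tile).
#' @export
#' @examples
#' ig <- render_interferogram(build_scene(magnification = 5, seed = 1),
#'                            noise_sd = 0, seed = 1)
#' m <- segment_tiles(ig)
#' pixel_accuracy(m, ig$tile_mask)
segment_tiles <- function(image, model = NULL, sat_thr = 0.10,
                          bright_tol = 0.18, min_bar_frac = 0.01) {
  img <- as_image_array(image)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  if (min(h, w) < 16L) stop("image too small to contain a grid square", call. = FALSE)
  if (!is.null(model)) {
    return(predict_seg_model(model, img))
  }
  b <- brightness_of(img)
  s <- saturation_of(img)
  cand <- s < sat_thr & b > 0.35
  if (mean(cand) < min_bar_frac) {
    warning("no grid bars found; returning an empty tile mask")
    return(matrix(0, h, w))
  }
  bar_level <- stats::median(b[cand])
  bar <- s < sat_thr + 0.02 & abs(b - bar_level) < bright_tol
  bar <- from_ebimage(EBImage::closing(as_ebimage(bar * 1),
                                       EBImage::makeBrush(3, "box"))) > 0.5
  matrix(as.numeric(!bar), h, w)
}

#' Post-process a tile mask into individual detections
#'
#' Connected-component analysis (4-connectivity) of the tile mask with the
#' standard clean-up applied after segmentation: holes inside each
#' component are filled, components with an over-elongated bounding box
#' (aspect ratio above `max_aspect`) or a too-small area are removed, and
#' the surviving detections are returned sorted row-major by bounding-box
#' origin. Components touching the image border are kept but flagged.
#'
#' @param mask 0/1 tile mask.
#' @param max_aspect Maximum allowed bounding-box aspect ratio
#'   (max side / min side).
#' @param min_area Minimum component area in px, or `NULL` to use
#'   `min_area_frac` of the median component area.
#' @param min_area_frac Fraction of the median area used when `min_area`
#'   is NULL.
#' @return A list of `tile_detection` objects: `id`, `bbox` (0-based
#'   half-open `row0, col0, row1, col1`), `mask` (cropped to the bbox),
#'   `area`, `aspect`, `touches_border`.
#' @export
postprocess_mask <- function(mask, max_aspect = 1.5, min_area = NULL,
                             min_area_frac = 0.25) {
  if (!is_binary_mask(mask)) stop("`mask` must be a 0/1 matrix", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask == 1)) return(list())
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask)))
  n <- max(lab)
  comps <- lapply(seq_len(n), function(k) which(lab == k, arr.ind = TRUE))
  areas <- vapply(comps, nrow, 1L)
  if (is.null(min_area)) min_area <- min_area_frac * stats::median(areas)
  out <- list()
  for (k in seq_len(n)) {
    idx <- comps[[k]]
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    hgt <- r1 - r0 + 1L; wid <- c1 - c0 + 1L
    aspect <- max(hgt, wid) / min(hgt, wid)
    sub <- matrix(0, hgt, wid)
    sub[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1
    sub <- from_ebimage(EBImage::fillHull(as_ebimage(sub)))
    area <- sum(sub)
    touches <- r0 == 1L || c0 == 1L || r1 == h || c1 == w
    if (touches) {
      # Border-touching partial squares are legitimately asymmetric: keep
      # them flagged rather than filtered, unless they are specks.
      if (area < 25) next
    } else if (aspect > max_aspect || area < min_area) {
      next
    }
    out[[length(out) + 1L]] <- structure(list(
      id = NA_integer_,
      bbox = c(row0 = r0 - 1L, col0 = c0 - 1L, row1 = r1, col1 = c1),
      mask = sub, area = area, aspect = aspect,
      touches_border = touches
    ), class = "tile_detection")
  }
  if (!length(out)) return(out)
  ord <- order(vapply(out, function(d) d$bbox[["row0"]], 0),
               vapply(out, function(d) d$bbox[["col0"]], 0))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Union of detection masks on the full raster
#'
#' @param detections List from [postprocess_mask()].
#' @param dim Raster size `c(nrow, ncol)`.
#' @return A 0/1 mask matrix.
#' @export
detections_to_mask <- function(detections, dim) {
  m <- matrix(0, dim[1L], dim[2L])
  for (d in detections) {
    bb <- d$bbox
    rr <- (bb[["row0"]] + 1L):bb[["row1"]]
    cc <- (bb[["col0"]] + 1L):bb[["col1"]]
    m[rr, cc] <- pmax(m[rr, cc], d$mask)
  }
  m
}

#' Pixel accuracy between two binary masks
#'
#' Fraction of pixels on which a predicted tile/background mask agrees with
#' the ground truth.
#'
#' @param predicted,truth 0/1 matrices of identical shape.
#' @return A fraction in [0, 1].
#' @export
pixel_accuracy <- function(predicted, truth) {
  if (!is_binary_mask(predicted) || !is_binary_mask(truth)) {
    stop("masks must be 0/1 matrices", call. = FALSE)
  }
  if (!identical(dim(predicted), dim(truth))) {
    stop("mask shapes differ", call. = FALSE)
  }
  mean(predicted == truth)
}

#' Augment a labelled image/mask pair
#'
#' Produces exactly four additional labelled copies of a training pair: two
#' randomly rotated copies and two random crops of random size and
#' position, with the mask transformed identically to the image (bilinear
#' for the image, nearest-neighbour for the mask). Deterministic per seed.
#'
#' @param image `H x W x 3` array (or `interferogram`).
#' @param mask Matching 0/1 mask.
#' @param seed Integer seed.
#' @param min_frac Minimum crop side as a fraction of the image side.
#' @param max_retries Retries for a too-small crop draw before erroring.
#' @param rot_angles Optional length-2 override of the rotation draws
#'   (degrees), e.g. `c(0, 0)` for identity copies.
#' @return A list of four `list(image, mask)` pairs (two `rotation`, two
#'   `crop`; see the `kind` field).
#' @export
augment <- function(image, mask, seed = 1L, min_frac = 0.3,
                    max_retries = 10L, rot_angles = NULL) {
  img <- as_image_array(image)
  if (!is_binary_mask(mask) || !identical(dim(mask), dim(img)[1:2])) {
    stop("`mask` must be a 0/1 matrix matching the image", call. = FALSE)
  }
  with_seed(seed, {
    out <- vector("list", 4L)
    angles <- if (is.null(rot_angles)) stats::runif(2, 0, 360) else rep_len(rot_angles, 2L)
    for (i in 1:2) {
      a <- angles[i]
      if (a %% 360 == 0) {
        out[[i]] <- list(image = img, mask = mask, kind = "rotation", angle = a)
      } else {
        ri <- from_ebimage(EBImage::rotate(as_ebimage(img), a, bg.col = 0))
        rm_ <- from_ebimage(EBImage::rotate(as_ebimage(mask), a, filter = "none",
                                            bg.col = 0))
        out[[i]] <- list(image = clamp01(ri), mask = round(rm_),
                         kind = "rotation", angle = a)
      }
    }
    h <- dim(img)[1L]; w <- dim(img)[2L]
    for (i in 3:4) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        ch <- round(stats::runif(1, min_frac, 1) * h)
        cw <- round(stats::runif(1, min_frac, 1) * w)
        if (ch < 16 || cw < 16) next
        r0 <- sample.int(h - ch + 1L, 1L)
        c0 <- sample.int(w - cw + 1L, 1L)
        sub_i <- img[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), , drop = FALSE]
        sub_m <- mask[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L)]
        out[[i]] <- list(image = sub_i, mask = sub_m, kind = "crop",
                         bbox = c(r0, c0, ch, cw))
        ok <- TRUE
        break
      }
      if (!ok) stop("could not draw a crop above the minimum size", call. = FALSE)
    }
    out
  })
}
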