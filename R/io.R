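#' Read an image file as an array
#'
#' Reads 8- or 16-bit PNG and TIFF images and returns an `H x W x 3` array
#' in [0, 1]; grayscale images are replicated across channels, alpha
#' channels dropped.
#'
#' @param path Image file path.
#' @return An `H x W x 3` array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  )
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3L] == 2L) a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  a
}

#' Write an image array to PNG or TIFF
#'
#' @param image Matrix or `H x W x 3` array in [0, 1].
#' @param path Destination; format chosen by extension (.png, .tif/.tiff;
#'   TIFF is written as 32-bit float, PNG as 8-bit).
#' @export
write_image <- function(image, path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = png::writePNG(clamp01(image), path),
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 32L),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE)
  )
  invisible(path)
}

#' Write / read an analysis report as JSON
#'
#' @param report An `analysis_report` from [analyze_image()].
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  payload <- report[setdiff(names(report), "overlay")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 8,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rep) <- "analysis_report"
  rep
}

# Atomic write: write to a hidden temp file in the target directory, then
# rename. Readers never observe partial outputs.
write_atomic <- function(writer, path) {
  tmp <- file.path(dirname(path), paste0(".tmp_", basename(path)))
  ok <- FALSE
  tryCatch({
    writer(tmp)
    file.rename(tmp, path)
    ok <- TRUE
  }, finally = if (!ok && file.exists(tmp)) unlink(tmp))
  invisible(path)
}

#' Summarise per-square EM thickness into a CSV row set
#'
#' @param summaries Named list of [square_summary()] objects (names = square
#'   ids).
#' @param path Optional CSV destination.
#' @return A data.frame with one row per square: id, the hole means, the
#'   overall mean and SD.
#' @export
summaries_to_csv <- function(summaries, path = NULL) {
  n_h <- max(vapply(summaries, function(s) length(s$hole_means), 0L))
  rows <- lapply(names(summaries), function(id) {
    s <- summaries[[id]]
    hm <- c(s$hole_means, rep(NA_real_, n_h - length(s$hole_means)))
    df <- data.frame(square_id = id, mean_nm = s$mean, sd_nm = s$sd)
    hm_df <- as.data.frame(as.list(hm))
    names(hm_df) <- paste0("hole_", seq_len(n_h))
    cbind(df, hm_df)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
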