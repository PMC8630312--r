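#' Raster image with acquisition metadata
#'
#' The basic unit consumed by every stage of the pipeline: a 2D grayscale
#' intensity matrix plus the physical metadata needed to report downstream
#' quantities in micrometres and hours. The first array axis is y (rows), the
#' second is x (columns); x is the applied-stretch direction. Pixel
#' coordinates are 0-based with the origin at the centre of the top-left
#' pixel.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param frame_interval_min Optional time between frames in minutes (> 0);
#'   required only for velocity analyses.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_size_um, frame_interval_min = NULL) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.null(frame_interval_min)) {
    if (!is.numeric(frame_interval_min) || length(frame_interval_min) != 1L ||
        !is.finite(frame_interval_min) || frame_interval_min <= 0)
      stop("`frame_interval_min` must be a single positive number")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min),
    class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster_image: %d x %d px, %.4g um/px", ncol(x$pixels),
              nrow(x$pixels), x$pixel_size_um))
  if (!is.null(x$frame_interval_min))
    cat(sprintf(", dt = %.4g min", x$frame_interval_min))
  cat(sprintf(", intensity [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_raster_image <- function(x) inherits(x, "raster_image")

#' Load a grayscale TIFF as one or more raster images
#'
#' Reads single- or multi-page grayscale TIFF files (8/16-bit integer or
#' float). Integer intensities are preserved bit-exactly (stored as doubles);
#' page order is preserved for stacks. Acquisition metadata is supplied by
#' the caller rather than parsed from TIFF tags, which are unreliable across
#' microscopes.
#'
#' @param path Path to a TIFF file.
#' @inheritParams raster_image
#' @return A `raster_image` for single-page files, otherwise a list of
#'   `raster_image` in page order.
#' @export
load_image <- function(path, pixel_size_um, frame_interval_min = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  imgs <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1L]
      else stop("RGB/multi-channel TIFF pages are not supported; ",
                "supply a grayscale image")
    }
    if (length(p) == 0L) stop("zero-size TIFF page")
    raster_image(p, pixel_size_um, frame_interval_min)
  })
  if (length(imgs) == 1L) imgs[[1L]] else imgs
}

#' Write a raster image (or list of them) to a TIFF file
#'
#' Integer-valued images are written as 16-bit (or 8-bit if `bits = 8`)
#' TIFF preserving values exactly; non-integer images are written as 32-bit
#' float.
#'
#' @param img A `raster_image` or list of them (multi-page output).
#' @param path Output path.
#' @param bits Bit depth for integer data (8 or 16).
#' @export
save_image <- function(img, path, bits = 16L) {
  imgs <- if (is_raster_image(img)) list(img) else img
  stopifnot(all(vapply(imgs, is_raster_image, logical(1))))
  maxv <- 2^bits - 1
  pages <- lapply(imgs, function(im) {
    p <- im$pixels
    if (all(p == round(p)) && min(p) >= 0 && max(p) <= maxv) {
      p / maxv
    } else {
      attr(p, "float") <- TRUE
      p
    }
  })
  is_float <- any(vapply(pages, function(p) isTRUE(attr(p, "float")), logical(1)))
  if (is_float) {
    tiff::writeTIFF(lapply(pages, function(p) { attr(p, "float") <- NULL
      matrix(as.numeric(p), nrow(p)) }), path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

#' Write a per-cell results table to CSV
#'
#' One row per cell with centroid (micrometres), shape metrics, strain
#' tensor components and the inclusion flag. Values round-trip through
#' [read_cell_table()] to at least 9 significant digits.
#'
#' @param records A data frame of cell records, as produced by
#'   [per_cell_strain()] / [shape_metrics()].
#' @param path Output CSV path.
#' @export
write_cell_table <- function(records, path) {
  cols <- c("cell_id", "centroid_x_um", "centroid_y_um", "area_um2",
            "perimeter_um", "eccentricity", "e_xx", "e_yy", "e_xy",
            "included_flag")
  df <- as.data.frame(records)
  for (cl in setdiff(cols, names(df))) df[[cl]] <- rep(NA, nrow(df))
  df <- df[, cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell results table written by [write_cell_table()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_cell_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a JSON run-metadata sidecar
#'
#' Records the configuration, seed and package version next to the numeric
#' outputs so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param config Configuration list (see [default_config()]).
#' @param seed Integer seed used for the run (or `NULL`).
#' @param extra Optional named list merged into the sidecar.
#' @export
write_run_metadata <- function(path, config, seed = NULL, extra = list()) {
  meta <- c(list(
    package = "cellstrain",
    version = as.character(utils::packageVersion("cellstrain")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
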