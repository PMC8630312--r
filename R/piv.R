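#' Particle image velocimetry on one frame pair
#'
#' FFT-based normalised cross-correlation over a grid of interrogation
#' windows with parabolic subpixel peak interpolation. Window displacement
#' is converted to micrometres per hour using the pixel size and frame
#' interval carried by the frames. Vectors whose correlation
#' signal-to-noise (primary peak / secondary peak) falls below `snr_min`,
#' or that lie more than 3 SD from the field median, are flagged invalid;
#' invalid vectors are excluded from statistics, never zero-filled or
#' interpolated (interpolation would bias the mean-speed statistic).
#'
#' @param frame_a,frame_b Consecutive [raster_image()] frames of identical
#'   shape with `frame_interval_min` set.
#' @param window Interrogation window size `c(w_x, w_y)` in pixels
#'   (default c(96, 48)).
#' @param overlap_fraction Window overlap; 0.5 gives grid spacing of half a
#'   window in each axis (default 0.5).
#' @param max_shift_px Search half-width (default `min(window) / 4`).
#' @param snr_min Minimum peak1/peak2 ratio (default 1.3).
#' @return A `velocity_field`: grid vectors `x`, `y` (px), matrices `v_x`,
#'   `v_y` (um/h), `valid`, `snr`, plus `pixel_size_um` and
#'   `frame_interval_min`.
#' @export
piv_pair <- function(frame_a, frame_b, window = c(96, 48),
                     overlap_fraction = 0.5, max_shift_px = NULL,
                     snr_min = 1.3) {
  stopifnot(is_raster_image(frame_a), is_raster_image(frame_b))
  if (!all(dim(frame_a$pixels) == dim(frame_b$pixels)))
    stop("frames must have identical shape")
  if (is.null(frame_a$frame_interval_min))
    stop("frames must carry `frame_interval_min`")
  if (length(window) == 1L) window <- rep(window, 2L)
  wx <- as.integer(window[1]); wy <- as.integer(window[2])
  a <- frame_a$pixels; b <- frame_b$pixels
  ny <- nrow(a); nx <- ncol(a)
  if (wx > nx || wy > ny) stop("interrogation window larger than image")
  max_shift_px <- as.integer(max_shift_px %||% max(4L, min(wx, wy) %/% 4L))
  step_x <- max(1L, as.integer(round(wx * (1 - overlap_fraction))))
  step_y <- max(1L, as.integer(round(wy * (1 - overlap_fraction))))
  x0 <- seq(1L, nx - wx + 1L, by = step_x)
  y0 <- seq(1L, ny - wy + 1L, by = step_y)
  gx <- x0 - 1 + (wx - 1) / 2     # window centre, 0-based px
  gy <- y0 - 1 + (wy - 1) / 2

  s <- max_shift_px
  v_x <- matrix(NA_real_, length(gy), length(gx))
  v_y <- matrix(NA_real_, length(gy), length(gx))
  snr <- matrix(NA_real_, length(gy), length(gx))
  for (j in seq_along(x0)) {
    for (i in seq_along(y0)) {
      ar <- y0[i]:(y0[i] + wy - 1L); ac <- x0[j]:(x0[j] + wx - 1L)
      # search patch from frame_b, edge-clamped at the borders
      br <- pmin(pmax((ar[1] - s):(ar[wy] + s), 1L), ny)
      bc <- pmin(pmax((ac[1] - s):(ac[wx] + s), 1L), nx)
      blk_a <- a[ar, ac, drop = FALSE]
      blk_b <- b[br, bc, drop = FALSE]
      res <- ncc_peak(blk_a, blk_b, s)
      if (is.null(res)) next
      v_x[i, j] <- res$shift[1]
      v_y[i, j] <- res$shift[2]
      snr[i, j] <- peak_snr(res$cc)
    }
  }
  valid <- !is.na(v_x) & snr >= snr_min
  # global outlier cut at 3 SD from the median vector
  if (sum(valid, na.rm = TRUE) >= 4) {
    mag_ok <- valid
    for (comp in c("x", "y")) {
      v <- if (comp == "x") v_x else v_y
      med <- stats::median(v[valid]); sdv <- stats::sd(v[valid])
      if (is.finite(sdv) && sdv > 0)
        mag_ok <- mag_ok & abs(v - med) <= 3 * sdv
    }
    valid <- mag_ok & valid
  }
  scale <- frame_a$pixel_size_um * 60 / frame_a$frame_interval_min  # px -> um/h
  structure(list(x = gx, y = gy, v_x = v_x * scale, v_y = v_y * scale,
                 valid = valid, snr = snr,
                 pixel_size_um = frame_a$pixel_size_um,
                 frame_interval_min = frame_a$frame_interval_min),
            class = "velocity_field")
}

# Ratio of primary correlation peak to the highest peak outside its
# 3x3 neighbourhood (a standard PIV vector-quality measure).
peak_snr <- function(cc) {
  im <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  p1 <- cc[im[1], im[2]]
  mask <- cc
  r1 <- max(1, im[1] - 1):min(nrow(cc), im[1] + 1)
  c1 <- max(1, im[2] - 1):min(ncol(cc), im[2] + 1)
  mask[r1, c1] <- -Inf
  p2 <- max(mask)
  if (!is.finite(p2) || p2 <= 0) return(Inf)
  p1 / p2
}

#' Hourly mean-speed series from a sequence of velocity fields
#'
#' Each field contributes the mean speed (mean of valid vector magnitudes,
#' a motility measure) for its frame pair; fields are grouped into hourly
#' bins of `frames_per_hour` consecutive pairs and averaged. A partial
#' trailing hour is dropped with a warning.
#'
#' @param fields List of `velocity_field` objects in temporal order.
#' @param frames_per_hour Frame pairs per hourly bin (default 6, i.e.
#'   10-minute frames).
#' @return A `speed_series` data frame: `hour`, `mean_speed_um_h`,
#'   `sd_um_h` (SD over the bin's per-field means), `n_fields`.
#' @export
mean_speed_per_hour <- function(fields, frames_per_hour = 6) {
  if (length(fields) == 0L) stop("no velocity fields supplied")
  stopifnot(all(vapply(fields, inherits, logical(1), "velocity_field")))
  per_field <- vapply(fields, function(f) {
    sp <- sqrt(f$v_x[f$valid]^2 + f$v_y[f$valid]^2)
    if (length(sp) == 0L) NA_real_ else mean(sp)
  }, numeric(1))
  n_bins <- length(per_field) %/% frames_per_hour
  if (n_bins == 0L) stop("fewer fields than one hourly bin")
  if (length(per_field) %% frames_per_hour != 0L)
    warning("dropping partial trailing hour (",
            length(per_field) %% frames_per_hour, " fields)")
  idx <- rep(seq_len(n_bins), each = frames_per_hour)
  used <- per_field[seq_along(idx)]
  out <- data.frame(
    hour = seq_len(n_bins),
    mean_speed_um_h = as.numeric(tapply(used, idx, mean, na.rm = TRUE)),
    sd_um_h = as.numeric(tapply(used, idx, stats::sd, na.rm = TRUE)),
    n_fields = as.integer(tapply(!is.na(used), idx, sum)))
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Normalize a speed series to a baseline bin
#'
#' Divides each hourly mean by the baseline bin's mean (by default the
#' first hour, i.e. the pre-stretch hour), making the baseline exactly 1.
#'
#' @param series A `speed_series` from [mean_speed_per_hour()].
#' @param baseline_bin Index of the baseline hour (default 1).
#' @return The series with a `normalized_speed` column added.
#' @export
normalize_speeds <- function(series, baseline_bin = 1) {
  stopifnot(inherits(series, "speed_series"),
            baseline_bin >= 1, baseline_bin <= nrow(series))
  base <- series$mean_speed_um_h[baseline_bin]
  if (!is.finite(base) || base <= 0)
    stop("baseline mean speed must be positive")
  series$normalized_speed <- series$mean_speed_um_h / base
  series
}
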