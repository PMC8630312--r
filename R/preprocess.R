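#' Gaussian smoothing at a stated pixel scale
#'
#' Small-kernel Gaussian filter applied before registration. The smoothing
#' scale is given as a full width at half maximum in pixels; the kernel has
#' odd support so the filter is symmetric and shift-free, and reflect
#' padding is used at the image boundary so constants are preserved and
#' total intensity is conserved to well under 0.1% for interior-dominated
#' images.
#'
#' @param image A [raster_image()].
#' @param kernel_px Smoothing scale (FWHM) in pixels, >= 1. Default 2.
#' @return A smoothed `raster_image` of the same shape.
#' @export
gaussian_smooth <- function(image, kernel_px = 2) {
  stopifnot(is_raster_image(image))
  if (!is.numeric(kernel_px) || length(kernel_px) != 1L || kernel_px < 1)
    stop("`kernel_px` must be a single value >= 1")
  sigma <- kernel_px / (2 * sqrt(2 * log(2)))  # FWHM -> sigma
  k <- gaussian_kernel_1d(sigma)
  image$pixels <- sep_convolve_reflect(image$pixels, k)
  image
}

# Odd-support normalised 1D Gaussian kernel (radius = ceil(3 sigma)).
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with reflect padding.
sep_convolve_reflect <- function(px, k) {
  r <- (length(k) - 1L) %/% 2L
  p <- reflect_pad(px, r)
  # rows (y direction)
  p <- apply_kernel_dim(p, k, 1L)
  p <- apply_kernel_dim(p, k, 2L)
  p[(r + 1):(r + nrow(px)), (r + 1):(r + ncol(px)), drop = FALSE]
}

apply_kernel_dim <- function(p, k, dim) {
  r <- (length(k) - 1L) %/% 2L
  out <- p * k[r + 1L]
  for (s in seq_len(r)) {
    if (dim == 1L) {
      n <- nrow(p)
      up <- p[c(seq_len(s) * 0 + 1L, seq_len(n - s)), , drop = FALSE]
      dn <- p[c(seq(s + 1L, n), rep(n, s)), , drop = FALSE]
    } else {
      n <- ncol(p)
      up <- p[, c(seq_len(s) * 0 + 1L, seq_len(n - s)), drop = FALSE]
      dn <- p[, c(seq(s + 1L, n), rep(n, s)), drop = FALSE]
    }
    out <- out + k[r + 1L + s] * (up + dn)
  }
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast normalisation that corrects uneven illumination before
#' registration. The image is min-max normalised to [0, 1], equalised on a
#' tile grid with a relative clip limit, and returned in [0, 1]. A constant
#' image is returned unchanged (there is no contrast to equalise).
#'
#' @param image A [raster_image()].
#' @param tile_grid Integer pair: number of tiles in (x, y). Default c(8, 8).
#' @param clip_limit Clip limit as a fraction of the tile histogram mass in
#'   (0, 1]. Default 0.01.
#' @return A `raster_image` with intensities in [0, 1].
#' @export
equalize_clahe <- function(image, tile_grid = c(8, 8), clip_limit = 0.01) {
  stopifnot(is_raster_image(image))
  if (length(tile_grid) == 1L) tile_grid <- rep(tile_grid, 2L)
  if (any(tile_grid < 1)) stop("`tile_grid` must be positive")
  if (prod(tile_grid) < 4)
    stop("`tile_grid` must contain at least 4 tiles")
  if (clip_limit <= 0 || clip_limit > 1)
    stop("`clip_limit` must be in (0, 1]")
  px <- image$pixels
  if (diff(range(px)) <= 0) {
    image$pixels <- px * 0 + min(1, max(0, px[1]))
    return(image)
  }
  bins <- 256L
  # EBImage's `limit` is a multiple of the uniform histogram height;
  # a clip fraction c of the tile mass corresponds to limit = c * bins.
  out <- EBImage::clahe(mat_to_eb(norm01(px)),
                        nx = as.integer(tile_grid[1]),
                        ny = as.integer(tile_grid[2]),
                        bins = bins,
                        limit = clip_limit * bins)
  image$pixels <- pmin(pmax(eb_to_mat(out), 0), 1)
  image
}

#' Condition an image pair identically before registration
#'
#' Applies the standard two-step conditioning (Gaussian smoothing, then
#' CLAHE) to both members of a registration pair with identical parameters.
#' Asymmetric preprocessing would bias the registration and is deliberately
#' impossible through this interface.
#'
#' @param reference,deformed [raster_image()] pair.
#' @param gaussian_px Smoothing FWHM in pixels (see [gaussian_smooth()]).
#' @param clahe_tiles,clahe_clip CLAHE parameters (see [equalize_clahe()]).
#' @param use_clahe Apply the CLAHE step (default `TRUE`).
#' @return A list with elements `reference` and `deformed`.
#' @export
preprocess_pair <- function(reference, deformed, gaussian_px = 2,
                            clahe_tiles = c(8, 8), clahe_clip = 0.01,
                            use_clahe = TRUE) {
  one <- function(im) {
    im <- gaussian_smooth(im, gaussian_px)
    if (use_clahe) im <- equalize_clahe(im, clahe_tiles, clahe_clip)
    im
  }
  list(reference = one(reference), deformed = one(deformed))
}
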