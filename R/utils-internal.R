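# Internal numeric helpers shared across modules.
#
# Coordinate convention (package-wide): pixel (x, y) with x along the second
# array axis (columns) and y along the first (rows); 0-based coordinates with
# the origin at the centre of the top-left pixel. x is the applied-stretch
# direction.

#' @keywords internal
px_at <- function(px, ix, iy) px[iy + 1L + ix * nrow(px)]

# Bilinear interpolation at continuous (x, y); NA outside the image footprint.
bilinear_sample <- function(px, x, y) {
  ny <- nrow(px); nx <- ncol(px)
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 &
    is.finite(x) & is.finite(y)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  x0[!ok] <- 0; y0[!ok] <- 0
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * ny
  v <- (1 - fx) * (1 - fy) * px[i00] +
    (1 - fx) * fy  * px[i00 + 1] +
    fx * (1 - fy)  * px[i00 + ny] +
    fx * fy        * px[i00 + ny + 1]
  v[!ok] <- NA_real_
  v
}

# Bilinear sampling with edge replication instead of NA (used for resampling
# deformed movies where content flows in from outside the field).
bilinear_sample_clamp <- function(px, x, y) {
  ny <- nrow(px); nx <- ncol(px)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  bilinear_sample(px, x, y)
}

# 2x2 block-mean downsampling (odd trailing row/col dropped).
downsample2 <- function(px) {
  ny <- nrow(px) %/% 2L; nx <- ncol(px) %/% 2L
  a <- px[seq_len(2L * ny), seq_len(2L * nx), drop = FALSE]
  0.25 * (a[seq(1, 2 * ny, 2), seq(1, 2 * nx, 2)] +
            a[seq(2, 2 * ny, 2), seq(1, 2 * nx, 2)] +
            a[seq(1, 2 * ny, 2), seq(2, 2 * nx, 2)] +
            a[seq(2, 2 * ny, 2), seq(2, 2 * nx, 2)])
}

# Reflect-pad a matrix by k pixels on every side.
reflect_pad <- function(px, k) {
  ny <- nrow(px); nx <- ncol(px)
  stopifnot(k < ny, k < nx)
  ridx <- c(rev(seq_len(k) + 1L), seq_len(ny), ny - seq_len(k))
  cidx <- c(rev(seq_len(k) + 1L), seq_len(nx), nx - seq_len(k))
  px[ridx, cidx, drop = FALSE]
}

# Min-max normalisation to [0, 1]; constant images map to 0.
norm01 <- function(px) {
  r <- range(px, finite = TRUE)
  if (r[2] - r[1] <= 0) return(px * 0)
  (px - r[1]) / (r[2] - r[1])
}

# Matrix <-> EBImage conversion. EBImage stores images as (x, y); the package
# stores them as R matrices with rows = y, cols = x.
mat_to_eb <- function(px) EBImage::Image(t(px))
eb_to_mat <- function(img) t(EBImage::imageData(img))

# Run code with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
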