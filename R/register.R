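#' 2D affine transform (reference -> deformed frame)
#'
#' Maps reference-frame pixel coordinates x = (x, y) to deformed-frame
#' coordinates via `A %*% x + t`. The linear part must preserve orientation
#' (`det(A) > 0`): a physical stretch never reflects the monolayer.
#'
#' @param A 2x2 linear part (dimensionless).
#' @param t Length-2 translation in pixels.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(A = diag(2), t = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  t <- as.numeric(t)
  stopifnot(length(t) == 2L, all(is.finite(A)), all(is.finite(t)))
  if (det(A) <= 0) stop("affine transform must preserve orientation (det(A) > 0)")
  structure(list(A = A, t = t), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d: A = [%.5f %.5f; %.5f %.5f], t = (%.3f, %.3f) px\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2]))
  invisible(x)
}

#' Apply an affine transform to coordinates
#' @param transform An [affine2d()].
#' @param xy n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
affine_apply <- function(transform, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  sweep(xy %*% t(transform$A), 2L, transform$t, `+`)
}

#' Invert an affine transform
#' @inheritParams affine_apply
#' @export
affine_invert <- function(transform) {
  Ai <- solve(transform$A)
  affine2d(Ai, -as.numeric(Ai %*% transform$t))
}

#' Compose two affine transforms (`second` after `first`)
#' @param second,first [affine2d()] objects.
#' @export
affine_compose <- function(second, first) {
  affine2d(second$A %*% first$A,
           as.numeric(second$A %*% first$t) + second$t)
}

#' Small-strain tensor
#'
#' Dimensionless in-plane strain components in the chamber frame: `e_xx`
#' along the applied-stretch axis, `e_yy` transverse, `e_xy` the single
#' off-diagonal (shear) value of the symmetric tensor.
#'
#' @param e_xx,e_yy,e_xy Strain components; each must be finite and below
#'   `bound` in absolute value.
#' @param bound Validity bound on |component| (default 1).
#' @export
strain_tensor <- function(e_xx, e_yy, e_xy, bound = 1) {
  v <- c(e_xx = e_xx, e_yy = e_yy, e_xy = e_xy)
  if (any(!is.finite(v))) stop("strain components must be finite")
  if (any(abs(v) >= bound))
    stop("strain components exceed validity bound ", bound)
  structure(as.list(v), class = "strain_tensor")
}

#' Convert an affine transform to its small-strain tensor
#'
#' For an affine displacement field u(x) = (A - I) x + t the displacement
#' gradients are constant, so e_xx = A_xx - 1, e_yy = A_yy - 1 and
#' e_xy = (A_xy + A_yx) / 2 (the symmetric part of A - I). Translation
#' carries no strain. A pure rotation yields zero shear and equal negative
#' normal components (cos(theta) - 1), the expected small-strain artefact.
#'
#' @param transform An [affine2d()].
#' @return A [strain_tensor()].
#' @export
affine_to_strain <- function(transform) {
  A <- transform$A
  strain_tensor(A[1, 1] - 1, A[2, 2] - 1, (A[1, 2] + A[2, 1]) / 2)
}

# ---------------------------------------------------------------------------
# Mattes-style mutual information affine registration.

# Soft (linear partial-volume) joint histogram MI between two intensity
# vectors. Linear binning keeps the metric continuous in the transform
# parameters so a simplex optimizer can reach subpixel accuracy.
mutual_information <- function(a, b, nbins, range_a, range_b) {
  da <- range_a[2] - range_a[1]; db <- range_b[2] - range_b[1]
  if (da <= 0 || db <= 0) return(0)
  ca <- pmin(pmax((a - range_a[1]) / da, 0), 1) * (nbins - 1)
  cb <- pmin(pmax((b - range_b[1]) / db, 0), 1) * (nbins - 1)
  ia <- pmin(floor(ca), nbins - 2); fa <- ca - ia
  ib <- pmin(floor(cb), nbins - 2); fb <- cb - ib
  idx <- function(i, j) i + 1 + j * nbins
  w <- c((1 - fa) * (1 - fb), fa * (1 - fb), (1 - fa) * fb, fa * fb)
  id <- c(idx(ia, ib), idx(ia + 1, ib), idx(ia, ib + 1), idx(ia + 1, ib + 1))
  joint <- numeric(nbins * nbins)
  acc <- rowsum(w, id)
  joint[as.integer(rownames(acc))] <- acc
  joint <- joint / sum(joint)
  pj <- matrix(joint, nbins, nbins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

# Parameter vector p = (a11-1, a22-1, a12, a21, tx, ty), with the linear part
# acting about the image centre c: T(x) = A (x - c) + c + t. Centred
# parameterisation decorrelates scale and translation for the optimizer.
params_to_affine <- function(p, center) {
  A <- matrix(c(1 + p[1], p[4], p[3], 1 + p[2]), 2, 2)
  t <- center - as.numeric(A %*% center) + p[5:6]
  list(A = A, t = t)
}

affine_to_params <- function(transform, center) {
  A <- transform$A
  t_c <- transform$t - center + as.numeric(A %*% center)
  c(A[1, 1] - 1, A[2, 2] - 1, A[1, 2], A[2, 1], t_c[1], t_c[2])
}

neg_mi_objective <- function(ref_px, def_px, coords, ref_vals, nbins,
                             range_r, range_d, center) {
  function(p) {
    Tp <- params_to_affine(p, center)
    mapped <- sweep(coords %*% t(Tp$A), 2L, Tp$t, `+`)
    dv <- bilinear_sample(def_px, mapped[, 1], mapped[, 2])
    ok <- !is.na(dv)
    if (sum(ok) < 0.5 * length(dv)) return(1e6)  # insufficient overlap
    -mutual_information(ref_vals[ok], dv[ok], nbins, range_r, range_d)
  }
}

#' Register a deformed image onto a reference by affine transform
#'
#' Multi-resolution intensity-based affine registration driven by a Mattes
#' mutual-information metric with linear partial-volume binning. The
#' returned transform maps reference-frame coordinates into the deformed
#' frame. Both images should have passed through [preprocess_pair()] with
#' identical settings. The procedure is fully deterministic: samples are
#' taken on a fixed stride and the simplex optimizer uses no randomness.
#'
#' @param reference,deformed [raster_image()] pair of identical shape.
#' @param init Optional initial [affine2d()] (default identity).
#' @param pyramid_levels Number of resolution levels (default 3).
#' @param mi_bins Histogram bins for the MI metric (default 50).
#' @param max_samples Maximum pixel samples per metric evaluation
#'   (default 20000).
#' @param maxit Simplex iterations per optimizer run (default 400).
#' @param sample_region Central fraction of the field sampled for the
#'   metric (default 0.7). Restricting samples to a region that stays in
#'   bounds under the expected transforms keeps the sample count constant,
#'   which removes the overlap-dependence bias of mutual information.
#' @param restarts Simplex restarts per pyramid level (default 2; a
#'   restart rebuilds the simplex around the current optimum and guards
#'   against premature convergence).
#' @return A list with `transform` ([affine2d()]), `metric` (final mutual
#'   information, nats) and `metric_init` (at the initial transform).
#'   Registration failure (metric worse than at initialisation, or a
#'   transform outside physical validity bounds) raises an error carrying
#'   both metric values, never a silent identity.
#' @export
register_affine <- function(reference, deformed, init = NULL,
                            pyramid_levels = 3, mi_bins = 50,
                            max_samples = 20000, maxit = 400,
                            sample_region = 0.7, restarts = 2) {
  stopifnot(is_raster_image(reference), is_raster_image(deformed))
  if (!all(dim(reference$pixels) == dim(deformed$pixels)))
    stop("registration pair must have identical shape")
  if (diff(range(reference$pixels)) <= 0 || diff(range(deformed$pixels)) <= 0)
    stop("registration failure: degenerate (constant) intensity range")
  if (is.null(init)) init <- affine2d()

  ref_pyr <- list(reference$pixels)
  def_pyr <- list(deformed$pixels)
  for (l in seq_len(pyramid_levels - 1)) {
    if (min(dim(ref_pyr[[l]])) < 32) break
    ref_pyr[[l + 1]] <- downsample2(ref_pyr[[l]])
    def_pyr[[l + 1]] <- downsample2(def_pyr[[l]])
  }
  nlev <- length(ref_pyr)

  # Transform at full resolution; express at level l by scaling translation.
  full_center <- c(ncol(reference$pixels), nrow(reference$pixels)) / 2 - 0.5
  p <- affine_to_params(init, full_center)

  metric_init <- NA_real_
  metric_final <- NA_real_
  for (l in rev(seq_len(nlev))) {
    s <- 2^(l - 1)
    rp <- ref_pyr[[l]]; dp <- def_pyr[[l]]
    ny <- nrow(rp); nx <- ncol(rp)
    center_l <- c(nx, ny) / 2 - 0.5
    lo_x <- round(nx * (1 - sample_region) / 2); hi_x <- nx - 1L - lo_x
    lo_y <- round(ny * (1 - sample_region) / 2); hi_y <- ny - 1L - lo_y
    npx <- (hi_x - lo_x + 1) * (hi_y - lo_y + 1)
    stride <- max(1L, floor(sqrt(npx / max_samples)))
    xs <- seq(lo_x, hi_x, by = stride); ys <- seq(lo_y, hi_y, by = stride)
    coords <- cbind(rep(xs, each = length(ys)), rep(ys, length(xs)))
    rv <- rp[coords[, 2] + 1 + coords[, 1] * ny]
    obj <- neg_mi_objective(rp, dp, coords, rv, mi_bins,
                            range(rp), range(dp), center_l)
    p_l <- p; p_l[5:6] <- p[5:6] / s
    run_nm <- function(p0) {
      fit <- NULL
      for (r in seq_len(max(1L, restarts))) {
        fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = 1e-12,
                                           parscale = c(rep(0.02, 4), 1, 1)))
        p0 <- fit$par
      }
      fit
    }
    if (l == nlev) {
      # MI has a narrow capture range: a few pixels in translation and
      # roughly +/- 0.15 in scale at membrane-texture resolution. Explore
      # deterministic starts at the (cheap) coarsest level -- the plain
      # init, a translation seeded by a whole-field cross-correlation
      # scan, and x-scale offsets bracketing the physiological stretch
      # range -- and keep the best optimum.
      p_seed <- p_l
      p_seed[5:6] <- p_seed[5:6] + coarse_translation(rp, dp, p_l, center_l)
      starts <- list(p_l, p_seed)
      for (ds in c(-0.2, -0.1, 0.1, 0.2)) {
        ps <- p_l; ps[1] <- ps[1] + ds
        starts <- c(starts, list(ps))
      }
      fits <- lapply(unique(starts), function(p0)
        stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-12,
                                    parscale = c(rep(0.02, 4), 1, 1))))
      best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
      fit <- run_nm(best$par)
    } else {
      if (l == 1L) metric_init <- -obj(affine_to_params(init, full_center))
      fit <- run_nm(p_l)
    }
    p <- fit$par; p[5:6] <- fit$par[5:6] * s
    metric_final <- -fit$value
    if (nlev == 1L) metric_init <- -obj(affine_to_params(init, full_center))
  }

  Tp <- params_to_affine(p, full_center)
  strain_mag <- max(abs(c(Tp$A[1, 1] - 1, Tp$A[2, 2] - 1,
                          Tp$A[1, 2], Tp$A[2, 1])))
  if (det(Tp$A) <= 0 || strain_mag > 0.6)
    stop(sprintf(paste0("registration failure: transform outside validity ",
                        "bounds (max |A - I| = %.3f, det = %.3f)"),
                 strain_mag, det(Tp$A)))
  if (metric_final < metric_init - 1e-6)
    stop(sprintf(paste0("registration failure: metric worsened ",
                        "(init %.4f -> final %.4f nats)"),
                 metric_init, metric_final))
  list(transform = affine2d(Tp$A, Tp$t),
       metric = metric_final, metric_init = metric_init)
}

# Integer translation estimate at the coarsest pyramid level: normalised
# cross-correlation of the central reference block against the deformed
# image. Returns the (dx, dy) residual to add to the current translation.
coarse_translation <- function(rp, dp, p_l, center_l) {
  ny <- nrow(rp); nx <- ncol(rp)
  s <- max(2L, min(nx, ny) %/% 4L)
  hx <- nx %/% 4L; hy <- ny %/% 4L
  ac <- (center_l[1] - hx + 1):(center_l[1] + hx) + 0.5
  ar <- (center_l[2] - hy + 1):(center_l[2] + hy) + 0.5
  ac <- round(ac); ar <- round(ar)
  a <- rp[ar, ac, drop = FALSE]
  # current translation offsets the search patch
  t0 <- round(p_l[5:6])
  bc <- pmin(pmax((ac[1] - s):(ac[length(ac)] + s) + t0[1], 1L), nx)
  br <- pmin(pmax((ar[1] - s):(ar[length(ar)] + s) + t0[2], 1L), ny)
  res <- ncc_peak(a, dp[br, bc, drop = FALSE], s)
  if (is.null(res) || res$peak < 0.2) return(c(0, 0))
  t0 + res$shift - p_l[5:6]  # residual relative to the current translation
}

# ---------------------------------------------------------------------------
# Dense displacement refinement.

#' Dense block-wise displacement field
#'
#' Refines a global affine registration into a gridded displacement field:
#' each interrogation block in the reference image is matched, by normalised
#' cross-correlation with parabolic subpixel peak interpolation, to the
#' deformed image around its affine-predicted location. This resolves
#' spatial strain heterogeneity below the whole-image affine and is the
#' input to [per_cell_strain()]. Blocks whose correlation peak falls below
#' `corr_threshold` are flagged invalid rather than filled.
#'
#' @param reference,deformed Preprocessed [raster_image()] pair.
#' @param global_transform [affine2d()] from [register_affine()].
#' @param block_px Interrogation block size in pixels (>= 16, default 32).
#' @param search_px Search half-width around the predicted position
#'   (default 8).
#' @param grid_step Grid spacing in pixels (default `block_px / 4`).
#' @param corr_threshold Minimum correlation peak for a valid vector
#'   (default 0.5).
#' @return A `displacement_field`: list with grid vectors `x`, `y` (px),
#'   matrices `u_x`, `u_y` (px, displacement reference -> deformed) and
#'   logical matrix `valid`.
#' @export
dense_displacement <- function(reference, deformed, global_transform,
                               block_px = 32, search_px = 8,
                               grid_step = NULL, corr_threshold = 0.5) {
  stopifnot(is_raster_image(reference), is_raster_image(deformed))
  if (block_px < 16) stop("`block_px` must be >= 16")
  grid_step <- grid_step %||% max(4L, block_px %/% 4L)
  rp <- reference$pixels; dp <- deformed$pixels
  ny <- nrow(rp); nx <- ncol(rp)
  h <- block_px %/% 2L
  margin <- h
  gx <- seq(margin, nx - 1 - margin, by = grid_step)
  gy <- seq(margin, ny - 1 - margin, by = grid_step)
  if (length(gx) == 0 || length(gy) == 0)
    stop("image too small for the requested block size")

  u_x <- matrix(NA_real_, length(gy), length(gx))
  u_y <- matrix(NA_real_, length(gy), length(gx))
  valid <- matrix(FALSE, length(gy), length(gx))
  pk <- matrix(NA_real_, length(gy), length(gx))

  # reference block spans pixels (c - h):(c + h - 1); its geometric centre
  # is at c - 0.5. The deformed patch is sampled around the affine-mapped
  # centre so the search only recovers the residual (non-affine) part.
  off_int <- seq(-h, h - 1L)
  ex <- seq(-h - search_px, h + search_px - 1) + 0.5
  for (j in seq_along(gx)) {
    for (i in seq_along(gy)) {
      cx <- gx[j]; cy <- gy[i]
      a <- rp[cy + off_int + 1L, cx + off_int + 1L, drop = FALSE]
      ctr <- c(cx, cy) - 0.5
      map <- as.numeric(affine_apply(global_transform, rbind(ctr)))
      # window deformation: the search patch is sampled on the affine-
      # warped grid, so the global stretch is compensated and the
      # correlation peak measures only the residual displacement (an
      # uncompensated patch decorrelates under strain and locks onto
      # whichever membrane dominates the block)
      A <- global_transform$A
      Xi <- rep(ex, each = length(ex)); Eta <- rep(ex, length(ex))
      dxg <- map[1] + A[1, 1] * Xi + A[1, 2] * Eta
      dyg <- map[2] + A[2, 1] * Xi + A[2, 2] * Eta
      # a block whose search patch leaves the deformed field cannot be
      # matched honestly (stretch moves edge content out of view): flag it
      # invalid instead of clamping, which would bias the correlation
      b <- matrix(bilinear_sample(dp, dxg, dyg), length(ex), length(ex))
      if (anyNA(b)) next
      res <- ncc_peak(a, b, search_px)
      if (!is.null(res)) {
        pk[i, j] <- res$peak
        disp <- map - ctr + as.numeric(A %*% res$shift)
        u_x[i, j] <- disp[1]; u_y[i, j] <- disp[2]
        valid[i, j] <- res$peak >= corr_threshold
      }
    }
  }
  if (!any(valid)) stop("dense displacement failed: no valid blocks")
  structure(list(x = gx - 0.5, y = gy - 0.5, u_x = u_x, u_y = u_y,
                 valid = valid, peak = pk), class = "displacement_field")
}

# Normalised cross-correlation of block `a` (ay x ax) against the larger
# patch `b` (ay + 2s x ax + 2s); returns the subpixel peak shift (dx, dy)
# relative to the centred position and the peak correlation value. The
# numerator is computed by FFT (linear correlation: `a` occupies the
# top-left of a zero-padded array, so circular lags 0..2s are wrap-free);
# per-window means and norms of `b` come from integral images.
ncc_peak <- function(a, b, s) {
  ay <- nrow(a); ax <- ncol(a)
  a0 <- a - mean(a)
  na <- sqrt(sum(a0^2))
  if (na == 0) return(NULL)
  by <- nrow(b); bx <- ncol(b)
  apad <- matrix(0, by, bx)
  apad[seq_len(ay), seq_len(ax)] <- a0
  num_full <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(apad)),
                            inverse = TRUE)) / (by * bx)
  nshift <- 2L * s + 1L
  num <- num_full[seq_len(nshift), seq_len(nshift)]
  # integral images (zero-padded) for window sums of b and b^2
  win_sums <- function(m) {
    P <- rbind(0, cbind(0, t(apply(apply(m, 2, cumsum), 1, cumsum))))
    iy <- seq_len(nshift); ix <- seq_len(nshift)
    P[iy + ay, ix + ax, drop = FALSE] - P[iy, ix + ax, drop = FALSE] -
      P[iy + ay, ix, drop = FALSE] + P[iy, ix, drop = FALSE]
  }
  s1 <- win_sums(b); s2 <- win_sums(b^2)
  nb2 <- s2 - s1^2 / (ay * ax)
  cc <- ifelse(nb2 <= 0, 0, num / (na * sqrt(pmax(nb2, 1e-12))))
  im <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  peak <- cc[im[1], im[2]]
  sub <- c(parabolic_offset(cc, im, 2L), parabolic_offset(cc, im, 1L))
  shift <- c(im[2] - s - 1 + sub[1], im[1] - s - 1 + sub[2])
  list(shift = shift, peak = peak, cc = cc)
}

# 3-point parabolic subpixel offset along matrix dimension `dim` at peak `im`.
parabolic_offset <- function(cc, im, dim) {
  n <- dim(cc)[dim]
  i <- im[dim]
  if (i <= 1L || i >= n) return(0)
  cm <- if (dim == 1L) cc[i - 1L, im[2]] else cc[im[1], i - 1L]
  c0 <- if (dim == 1L) cc[i, im[2]] else cc[im[1], i]
  cp <- if (dim == 1L) cc[i + 1L, im[2]] else cc[im[1], i + 1L]
  den <- cm - 2 * c0 + cp
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (cm - cp) / den
  max(-0.5, min(0.5, off))
}
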