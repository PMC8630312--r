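#' Specification of a synthetic confluent monolayer
#'
#' Parameters of the ground-truthed image generator used to validate every
#' stage of the pipeline. The generator emulates a confluent epithelial
#' sheet imaged with a membrane marker: a Lloyd-relaxed Voronoi tessellation
#' of convex, roughly isotropic cells, bright membrane outlines, dim
#' cytoplasm with low-amplitude intracellular speckle (so intensity-based
#' registration and PIV have signal inside cells), and additive Gaussian
#' camera noise.
#'
#' @param field_px Field size in pixels, `c(nx, ny)` (a single value is
#'   square). Default 512.
#' @param pixel_size_um Micrometres per pixel. Default 0.5.
#' @param density_cells_per_mm2 Target cell density; the default 2200
#'   corresponds to a low-density epithelial monolayer (the regime
#'   2.0--2.5 x 10^3 cells/mm^2).
#' @param membrane_width_px Painted membrane thickness in pixels. Default 2.
#' @param levels Named intensity levels `c(background, cytoplasm, membrane)`
#'   in arbitrary camera units.
#' @param speckle_amp Intracellular speckle amplitude as a fraction of the
#'   cytoplasm level. Default 0.3.
#' @param noise_sd Additive Gaussian noise SD in camera units; if `NULL`,
#'   derived from `snr` as (membrane - cytoplasm) / snr.
#' @param snr Signal-to-noise ratio of the membrane contrast (used only
#'   when `noise_sd` is `NULL`). Default 10.
#' @param lloyd_iter Lloyd relaxation iterations (default 3).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `monolayer_spec`.
#' @export
monolayer_spec <- function(field_px = 512, pixel_size_um = 0.5,
                           density_cells_per_mm2 = 2200,
                           membrane_width_px = 2,
                           levels = c(background = 10, cytoplasm = 40,
                                      membrane = 200),
                           speckle_amp = 0.3, noise_sd = NULL, snr = 10,
                           lloyd_iter = 3, seed = 1) {
  if (length(field_px) == 1L) field_px <- rep(field_px, 2L)
  stopifnot(all(field_px >= 32), pixel_size_um > 0,
            density_cells_per_mm2 > 0, membrane_width_px >= 1)
  area_mm2 <- prod(field_px) * pixel_size_um^2 / 1e6
  n_cells <- round(density_cells_per_mm2 * area_mm2)
  if (n_cells < 2) stop("field too small for the requested density")
  cell_px2 <- prod(field_px) / n_cells
  if (cell_px2 < 4) stop("density too high: mean cell area below 4 px^2")
  if (is.null(noise_sd)) {
    if (snr <= 0) stop("`snr` must be positive")
    noise_sd <- (levels[["membrane"]] - levels[["cytoplasm"]]) / snr
  }
  structure(list(field_px = as.integer(field_px),
                 pixel_size_um = pixel_size_um,
                 density_cells_per_mm2 = density_cells_per_mm2,
                 n_cells = n_cells,
                 membrane_width_px = membrane_width_px,
                 levels = levels, speckle_amp = speckle_amp,
                 noise_sd = noise_sd, lloyd_iter = lloyd_iter,
                 seed = as.integer(seed)),
            class = "monolayer_spec")
}

# Nearest-seed (Euclidean) pixel assignment: the Voronoi label map.
voronoi_assign <- function(nx, ny, sx, sy) {
  X <- rep(seq_len(nx) - 1, each = ny)
  Y <- rep(seq_len(ny) - 1, nx)
  best_d <- rep(Inf, nx * ny)
  best_l <- integer(nx * ny)
  for (k in seq_along(sx)) {
    d <- (X - sx[k])^2 + (Y - sy[k])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_l[upd] <- k
  }
  matrix(best_l, ny, nx)
}

#' Generate a synthetic membrane-marker monolayer image with ground truth
#'
#' Seeds `n` points uniformly, Lloyd-relaxes the Voronoi tessellation so
#' cells are convex and size-homogeneous (as in a confluent epithelium),
#' paints membrane intensity along cell-cell boundaries, adds intracellular
#' speckle, and applies additive Gaussian noise last. The exact tessellation
#' is returned as the ground-truth label map.
#'
#' @param spec A [monolayer_spec()].
#' @return A list with `image` ([raster_image()]) and `labels` (integer
#'   matrix, cell k = label k; every pixel assigned).
#' @export
generate_monolayer <- function(spec) {
  stopifnot(inherits(spec, "monolayer_spec"))
  nx <- spec$field_px[1]; ny <- spec$field_px[2]
  with_seed(spec$seed, {
    sx <- stats::runif(spec$n_cells, 0, nx - 1)
    sy <- stats::runif(spec$n_cells, 0, ny - 1)
    lab <- voronoi_assign(nx, ny, sx, sy)
    for (it in seq_len(spec$lloyd_iter)) {
      X <- rep(seq_len(nx) - 1, each = ny)
      Y <- rep(seq_len(ny) - 1, nx)
      sx <- as.numeric(tapply(X, as.vector(lab), mean))
      sy <- as.numeric(tapply(Y, as.vector(lab), mean))
      lab <- voronoi_assign(nx, ny, sx, sy)
    }
    img <- paint_monolayer(lab, spec)
    list(image = raster_image(img, spec$pixel_size_um), labels = lab)
  })
}

# Membrane mask: pixels whose 4-neighbourhood crosses a label boundary,
# thickened to the requested width.
membrane_mask <- function(lab, width_px) {
  ny <- nrow(lab); nx <- ncol(lab)
  m <- matrix(FALSE, ny, nx)
  m[, -nx] <- m[, -nx] | (lab[, -nx] != lab[, -1])
  m[, -1]  <- m[, -1]  | (lab[, -1] != lab[, -nx])
  m[-ny, ] <- m[-ny, ] | (lab[-ny, ] != lab[-1, ])
  m[-1, ]  <- m[-1, ]  | (lab[-1, ] != lab[-ny, ])
  extra <- as.integer(width_px) - 2L
  if (extra > 0) {
    br <- EBImage::makeBrush(2L * ((extra + 1L) %/% 2L) + 1L, shape = "disc")
    m <- eb_to_mat(EBImage::dilate(mat_to_eb(m * 1), br)) > 0.5
  }
  m
}

# Paint intensities for a tessellation (noise applied last). Assumes the
# caller controls the RNG stream.
paint_monolayer <- function(lab, spec) {
  ny <- nrow(lab); nx <- ncol(lab)
  img <- matrix(spec$levels[["cytoplasm"]], ny, nx)
  if (spec$speckle_amp > 0) {
    sp <- matrix(stats::rnorm(nx * ny), ny, nx)
    sp <- sep_convolve_reflect(sp, gaussian_kernel_1d(1.2))
    sp <- sp / stats::sd(sp)
    img <- img + spec$speckle_amp * spec$levels[["cytoplasm"]] * sp
  }
  mem <- membrane_mask(lab, spec$membrane_width_px)
  img[mem] <- spec$levels[["membrane"]]
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nx * ny, 0, spec$noise_sd), ny, nx)
  pmax(img, 0)
}

#' Deformation specification for synthetic stretch
#'
#' Three modes mirror the experimental protocols: `uniform` applies one
#' affine strain state to the whole field (the nominal device behaviour);
#' `graded` imposes an `e_xx` that ramps linearly across the field (strain
#' inhomogeneity); `ramp` is a sequence of uniform `e_xx` states emulating
#' stepwise pressure increments.
#'
#' @param mode One of `"uniform"`, `"graded"`, `"ramp"`.
#' @param e_xx,e_yy,e_xy Strain components for `uniform` mode.
#' @param e_xx_range Length-2 `c(start, end)` of `e_xx` across x for
#'   `graded` mode.
#' @param steps Numeric vector of `e_xx` values for `ramp` mode.
#' @return An object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("uniform", "graded", "ramp"),
                             e_xx = 0, e_yy = 0, e_xy = 0,
                             e_xx_range = c(0, 0.1), steps = NULL) {
  mode <- match.arg(mode)
  if (mode == "ramp" && is.null(steps)) stop("`steps` required for ramp mode")
  structure(list(mode = mode, e_xx = e_xx, e_yy = e_yy, e_xy = e_xy,
                 e_xx_range = e_xx_range, steps = steps),
            class = "deformation_spec")
}

# Forward/inverse maps for the graded mode: the left edge (x = 0) is fixed,
# e_xx(x) = g0 + (g1 - g0) x / W, so u_x(x) = g0 x + (g1 - g0) x^2 / (2 W).
graded_forward_x <- function(x, g0, g1, W) {
  x + g0 * x + (g1 - g0) * x^2 / (2 * W)
}
graded_inverse_x <- function(xp, g0, g1, W) {
  a <- (g1 - g0) / (2 * W); b <- 1 + g0
  if (abs(a) < 1e-15) return(xp / b)
  (-b + sqrt(b^2 + 4 * a * xp)) / (2 * a)
}

#' Apply a known deformation to a synthetic monolayer
#'
#' Resamples the image through the exact deformation map (inverse-mapping
#' bilinear resampling, edge values replicated) and returns the per-cell
#' ground-truth strain tensor evaluated analytically: exact for uniform
#' mode, and the pointwise gradient at each cell centroid for graded mode.
#' Uniform deformations act about the field centre. A deformation whose
#' Jacobian is not positive everywhere (fold-over) is rejected.
#'
#' @param image A [raster_image()] (reference frame).
#' @param labels Ground-truth label matrix from [generate_monolayer()].
#' @param dspec A [deformation_spec()]; for `ramp` mode a list of deformed
#'   images and truth tables (one per step) is returned.
#' @return For `uniform`/`graded`: list with `image` (deformed
#'   [raster_image()]) and `truth` (data frame cell_id, e_xx, e_yy, e_xy).
#'   For `ramp`: list of such lists, one per step.
#' @export
apply_deformation <- function(image, labels, dspec) {
  stopifnot(is_raster_image(image), inherits(dspec, "deformation_spec"))
  px <- image$pixels
  ny <- nrow(px); nx <- ncol(px)
  cen <- cell_centroids(labels)

  if (dspec$mode == "ramp") {
    return(lapply(dspec$steps, function(e) {
      apply_deformation(image, labels,
                        deformation_spec("uniform", e_xx = e))
    }))
  }

  Xp <- rep(seq_len(nx) - 1, each = ny)   # deformed-frame coordinates
  Yp <- rep(seq_len(ny) - 1, nx)
  if (dspec$mode == "uniform") {
    E <- matrix(c(dspec$e_xx, dspec$e_xy, dspec$e_xy, dspec$e_yy), 2, 2)
    if (det(diag(2) + E) <= 0) stop("deformation folds over (det <= 0)")
    Ai <- solve(diag(2) + E)
    c0 <- c(nx, ny) / 2 - 0.5
    Xr <- Ai[1, 1] * (Xp - c0[1]) + Ai[1, 2] * (Yp - c0[2]) + c0[1]
    Yr <- Ai[2, 1] * (Xp - c0[1]) + Ai[2, 2] * (Yp - c0[2]) + c0[2]
    truth <- data.frame(cell_id = cen$cell_id,
                        e_xx = dspec$e_xx, e_yy = dspec$e_yy,
                        e_xy = dspec$e_xy)
  } else {
    g <- dspec$e_xx_range
    if (1 + max(g) <= 0 || 1 + min(g) <= 0)
      stop("deformation folds over (negative Jacobian)")
    Xr <- graded_inverse_x(Xp, g[1], g[2], nx - 1)
    Yr <- Yp
    truth <- data.frame(cell_id = cen$cell_id,
                        e_xx = g[1] + (g[2] - g[1]) * cen$x_px / (nx - 1),
                        e_yy = 0, e_xy = 0)
  }
  out <- matrix(bilinear_sample_clamp(px, Xr, Yr), ny, nx)
  image$pixels <- out
  list(image = image, truth = truth)
}

# Per-cell centroids (0-based px) of a label matrix.
cell_centroids <- function(lab) {
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  ny <- nrow(lab); nx <- ncol(lab)
  X <- rep(seq_len(nx) - 1, each = ny)
  Y <- rep(seq_len(ny) - 1, nx)
  v <- as.vector(lab)
  keep <- v > 0
  data.frame(cell_id = ids,
             x_px = as.numeric(tapply(X[keep], v[keep], mean)),
             y_px = as.numeric(tapply(Y[keep], v[keep], mean)))
}

#' Generate a drifting-monolayer time-lapse with ground-truth velocities
#'
#' Advects a monolayer texture with a programmed per-hour speed schedule
#' (uniform drift at a fixed heading), emulating slow collective motion
#' under time-lapse imaging. The base texture is generated on an enlarged
#' canvas so drifted frames never run out of content. Per-frame-pair
#' ground-truth velocities are returned.
#'
#' @param spec A [monolayer_spec()] (field size = output frame size).
#' @param speeds_um_per_h Per-hour speed schedule (vector, one value per
#'   hour), in micrometres per hour.
#' @param direction_deg Drift heading in degrees (0 = +x). Default 30.
#' @param frame_interval_min Minutes between frames. Default 10.
#' @param frame_noise_sd Additive per-frame Gaussian noise SD (camera
#'   units); defaults to `spec$noise_sd / 2`.
#' @return List with `frames` (list of [raster_image()], one per time
#'   point; `n_hours * frames_per_hour + 1` frames) and `truth` (data frame
#'   pair, v_x_um_h, v_y_um_h, speed_um_h).
#' @export
generate_timelapse <- function(spec, speeds_um_per_h, direction_deg = 30,
                               frame_interval_min = 10,
                               frame_noise_sd = NULL) {
  stopifnot(inherits(spec, "monolayer_spec"), all(speeds_um_per_h >= 0))
  frame_noise_sd <- frame_noise_sd %||% (spec$noise_sd / 2)
  fph <- as.integer(round(60 / frame_interval_min))
  n_pairs <- length(speeds_um_per_h) * fph
  shift_px <- rep(speeds_um_per_h, each = fph) *
    (frame_interval_min / 60) / spec$pixel_size_um
  th <- direction_deg * pi / 180
  dx <- cumsum(c(0, shift_px * cos(th)))
  dy <- cumsum(c(0, shift_px * sin(th)))

  nx <- spec$field_px[1]; ny <- spec$field_px[2]
  pad_x <- ceiling(max(abs(dx))) + 2L
  pad_y <- ceiling(max(abs(dy))) + 2L
  base_spec <- spec
  base_spec$field_px <- as.integer(c(nx + 2L * pad_x, ny + 2L * pad_y))
  area_scale <- prod(base_spec$field_px) / prod(spec$field_px)
  base_spec$n_cells <- max(2L, round(spec$n_cells * area_scale))
  base <- generate_monolayer(base_spec)$image$pixels

  Xp <- rep(seq_len(nx) - 1, each = ny)
  Yp <- rep(seq_len(ny) - 1, nx)
  with_seed(spec$seed + 1L, {
    frames <- lapply(seq_len(n_pairs + 1L), function(k) {
      # frame k shows the texture displaced by +d_k: sample base at x - d_k
      xs <- Xp + pad_x - dx[k]
      ys <- Yp + pad_y - dy[k]
      f <- matrix(bilinear_sample_clamp(base, xs, ys), ny, nx)
      if (frame_noise_sd > 0)
        f <- pmax(f + matrix(stats::rnorm(nx * ny, 0, frame_noise_sd), ny, nx), 0)
      raster_image(f, spec$pixel_size_um, frame_interval_min)
    })
    v <- shift_px * spec$pixel_size_um * (60 / frame_interval_min)
    truth <- data.frame(pair = seq_len(n_pairs),
                        v_x_um_h = v * cos(th), v_y_um_h = v * sin(th),
                        speed_um_h = v)
    list(frames = frames, truth = truth)
  })
}

#' Generate a cortical-marker image with programmed enrichment
#'
#' Emulates a cortex/cytoplasm marker (GFP-myosin analogue): every cell has
#' uniform cytoplasmic intensity; a programmed fraction of cells carries a
#' membrane-adjacent band at `enrichment_ratio` times the cytoplasmic
#' level. Ground-truth enrichment flags are returned.
#'
#' @param spec A [monolayer_spec()].
#' @param fraction_cortical Fraction of cells enriched, in [0, 1].
#' @param enrichment_ratio Band/interior intensity ratio (>= 1).
#' @param band_um Band width in micrometres (default 1.5).
#' @return List with `image` ([raster_image()]), `labels` (matrix) and
#'   `truth` (data frame cell_id, cortical).
#' @export
generate_cortical <- function(spec, fraction_cortical, enrichment_ratio,
                              band_um = 1.5) {
  stopifnot(inherits(spec, "monolayer_spec"),
            fraction_cortical >= 0, fraction_cortical <= 1,
            enrichment_ratio >= 1)
  mono <- generate_monolayer(spec)
  lab <- mono$labels
  n <- max(lab)
  with_seed(spec$seed + 2L, {
    n_enr <- round(fraction_cortical * n)
    enriched <- sort(sample.int(n, n_enr))
    cyto <- spec$levels[["cytoplasm"]]
    img <- matrix(cyto, nrow(lab), ncol(lab))
    band_px <- band_um / spec$pixel_size_um
    bands <- cell_band_interior(lab, band_px)
    for (id in enriched) img[bands$band_idx[[id]]] <- cyto * enrichment_ratio
    if (spec$noise_sd > 0)
      img <- pmax(img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                               nrow(img)), 0)
    list(image = raster_image(img, spec$pixel_size_um), labels = lab,
         truth = data.frame(cell_id = seq_len(n),
                            cortical = seq_len(n) %in% enriched))
  })
}
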