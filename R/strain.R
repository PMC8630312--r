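#' Per-cell strain tensors from a dense displacement field
#'
#' Fits, for each segmented cell, the local affine displacement model
#' u(x) = G x + c by least squares over the displacement-field grid points
#' falling inside the cell mask. The per-cell small-strain tensor is the
#' symmetric part of the fitted gradient: e_xx = G_xx, e_yy = G_yy,
#' e_xy = (G_xy + G_yx)/2. For a spatially uniform deformation this reduces
#' exactly to the global affine result; for heterogeneous fields it
#' resolves the strain at each cell. Cells with fewer than `min_samples`
#' valid grid points, or with a rank-deficient fit, are marked not included
#' with a reason.
#'
#' @param field A `displacement_field` from [dense_displacement()].
#' @param lmap Integer label matrix (reference frame).
#' @param min_samples Minimum valid grid points per cell (default 6).
#' @return A data frame with one row per cell: `cell_id`, `e_xx`, `e_yy`,
#'   `e_xy`, `n_samples`, `included_flag`, `exclude_reason`.
#' @export
per_cell_strain <- function(field, lmap, min_samples = 6) {
  stopifnot(inherits(field, "displacement_field"))
  ids <- setdiff(sort(unique(as.vector(lmap))), 0L)
  if (length(ids) == 0L)
    return(data.frame(cell_id = integer(0), e_xx = numeric(0),
                      e_yy = numeric(0), e_xy = numeric(0),
                      n_samples = integer(0), included_flag = logical(0),
                      exclude_reason = character(0)))
  gx <- rep(field$x, each = length(field$y))
  gy <- rep(field$y, length(field$x))
  ok <- as.vector(field$valid)
  glab <- lmap[cbind(round(gy) + 1L, round(gx) + 1L)]
  ux <- as.vector(field$u_x); uy <- as.vector(field$u_y)

  rows <- lapply(ids, function(id) {
    sel <- ok & glab == id
    n <- sum(sel)
    if (n < min_samples)
      return(data.frame(cell_id = id, e_xx = NA_real_, e_yy = NA_real_,
                        e_xy = NA_real_, n_samples = n,
                        included_flag = FALSE,
                        exclude_reason = "insufficient_displacement_samples"))
    M <- cbind(1, gx[sel], gy[sel])
    if (qr(M)$rank < 3L)
      return(data.frame(cell_id = id, e_xx = NA_real_, e_yy = NA_real_,
                        e_xy = NA_real_, n_samples = n,
                        included_flag = FALSE,
                        exclude_reason = "rank_deficient_fit"))
    cx <- qr.solve(M, ux[sel])   # u_x = c + G_xx x + G_xy y
    cy <- qr.solve(M, uy[sel])   # u_y = c + G_yx x + G_yy y
    data.frame(cell_id = id, e_xx = cx[2], e_yy = cy[3],
               e_xy = (cx[3] + cy[2]) / 2, n_samples = n,
               included_flag = TRUE, exclude_reason = "")
  })
  do.call(rbind, rows)
}

#' Cell-shape metrics from a label map
#'
#' Computes, per cell: area (pixel count scaled by the squared pixel
#' size), perimeter (crack-boundary length, i.e. the total length of
#' exposed pixel edges -- exact for axis-aligned rectangles, biased up to
#' 4/pi for smooth boundaries, a bias that cancels in the percent-change
#' comparisons this package reports), centroid, and eccentricity of the
#' moment-matched ellipse, e = sqrt(1 - (b/a)^2) with a >= b the
#' semi-axes. Single-pixel (or < 4 px) cells are flagged degenerate.
#'
#' @param lmap Integer label matrix.
#' @param pixel_size_um Micrometres per pixel.
#' @return A data frame: `cell_id`, `centroid_x_um`, `centroid_y_um`,
#'   `area_um2`, `perimeter_um`, `eccentricity`, `solidity`, `degenerate`.
#' @export
shape_metrics <- function(lmap, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  geom <- label_geometry(lmap)
  if (length(geom) == 0L)
    return(data.frame(cell_id = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), eccentricity = numeric(0),
                      solidity = numeric(0), degenerate = logical(0)))
  do.call(rbind, lapply(geom, function(g) data.frame(
    cell_id = g$cell_id,
    centroid_x_um = g$centroid_px[1] * pixel_size_um,
    centroid_y_um = g$centroid_px[2] * pixel_size_um,
    area_um2 = g$area_px * pixel_size_um^2,
    perimeter_um = g$perimeter_px * pixel_size_um,
    eccentricity = g$eccentricity,
    solidity = g$solidity,
    degenerate = g$degenerate)))
}

#' Percent changes in cell shape between matched before/after records
#'
#' Matches cells by `cell_id` (the deformed-frame label map is obtained by
#' mapping the reference masks through the registration transform, so ids
#' correspond) and reports the percent change of area, perimeter and
#' eccentricity per cell, plus mean and SD aggregates over matched cells.
#' Cells present in only one frame, or with a zero 'before' value, are
#' excluded and counted.
#'
#' @param before,after Data frames from [shape_metrics()].
#' @return List with `per_cell` (data frame of percent changes) and
#'   `summary` (data frame metric, mean_pct, sd_pct, n) and `n_unmatched`.
#' @export
shape_change <- function(before, after) {
  common <- intersect(before$cell_id, after$cell_id)
  n_unmatched <- length(union(before$cell_id, after$cell_id)) - length(common)
  b <- before[match(common, before$cell_id), ]
  a <- after[match(common, after$cell_id), ]
  pct <- function(x0, x1) ifelse(x0 == 0, NA_real_, 100 * (x1 - x0) / x0)
  per_cell <- data.frame(
    cell_id = common,
    area_pct = pct(b$area_um2, a$area_um2),
    perimeter_pct = pct(b$perimeter_um, a$perimeter_um),
    eccentricity_pct = pct(b$eccentricity, a$eccentricity))
  zero_before <- rowSums(cbind(b$area_um2 == 0, b$perimeter_um == 0)) > 0
  summ <- do.call(rbind, lapply(
    c("area_pct", "perimeter_pct", "eccentricity_pct"), function(m) {
      v <- per_cell[[m]][!zero_before]
      v <- v[is.finite(v)]
      data.frame(metric = sub("_pct$", "", m), mean_pct = mean(v),
                 sd_pct = stats::sd(v), n = length(v))
    }))
  list(per_cell = per_cell, summary = summ, n_unmatched = n_unmatched)
}

#' Map a reference-frame label map into the deformed frame
#'
#' Carries segmentation masks to the deformed frame through the recovered
#' registration transform (nearest-neighbour inverse mapping), so before
#' and after cells correspond by construction and no re-segmentation (with
#' its identity-switch risk) is needed.
#'
#' @param lmap Reference-frame integer label matrix.
#' @param transform [affine2d()] mapping reference to deformed coordinates.
#' @param dim_out Output dimensions `c(ny, nx)` (default: same as input).
#' @param expand If `TRUE`, enlarge (and offset) the output canvas to cover
#'   the whole transformed field, so cells near the edge are not clipped by
#'   the stretch; the pixel offset of the canvas origin is returned as
#'   attribute `"origin_px"`.
#' @return Integer label matrix in the deformed frame.
#' @export
map_labels <- function(lmap, transform, dim_out = dim(lmap),
                       expand = FALSE) {
  inv <- affine_invert(transform)
  origin <- c(0, 0)
  if (expand) {
    corners <- cbind(c(0, ncol(lmap) - 1, 0, ncol(lmap) - 1),
                     c(0, 0, nrow(lmap) - 1, nrow(lmap) - 1))
    mc <- affine_apply(transform, corners)
    lo <- floor(apply(mc, 2, min)); hi <- ceiling(apply(mc, 2, max))
    origin <- lo
    dim_out <- c(hi[2] - lo[2] + 1, hi[1] - lo[1] + 1)
  }
  ny <- dim_out[1]; nx <- dim_out[2]
  Xp <- rep(seq_len(nx) - 1, each = ny) + origin[1]
  Yp <- rep(seq_len(ny) - 1, nx) + origin[2]
  src <- affine_apply(inv, cbind(Xp, Yp))
  xi <- round(src[, 1]); yi <- round(src[, 2])
  ok <- xi >= 0 & xi <= ncol(lmap) - 1 & yi >= 0 & yi <= nrow(lmap) - 1
  out <- integer(nx * ny)
  out[ok] <- lmap[cbind(yi[ok] + 1L, xi[ok] + 1L)]
  structure(matrix(out, ny, nx), origin_px = origin)
}

#' Render a per-cell strain map overlay
#'
#' Writes a PNG in which each included cell is coloured by one strain
#' component on a diverging blue-white-red scale and excluded cells are
#' gray, the standard rendering for per-cell strain maps.
#'
#' @param lmap Label matrix of included cells.
#' @param records Data frame with `cell_id` and strain components.
#' @param component One of `"e_xx"`, `"e_yy"`, `"e_xy"`.
#' @param path Output PNG path.
#' @param excluded_labels Optional matrix of excluded cells (rendered gray).
#' @param limits Colour-scale limits (default symmetric about 0 at the 98th
#'   percentile of |value|).
#' @return The path, invisibly.
#' @export
plot_strain_map <- function(lmap, records, component = "e_xx", path,
                            excluded_labels = NULL, limits = NULL) {
  stopifnot(component %in% c("e_xx", "e_yy", "e_xy"))
  vals <- records[[component]][match(seq_len(max(lmap, 1)), records$cell_id)]
  if (is.null(limits)) {
    m <- stats::quantile(abs(vals), 0.98, na.rm = TRUE)
    if (!is.finite(m) || m == 0) m <- 1e-3
    limits <- c(-m, m)
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(255)
  ny <- nrow(lmap); nx <- ncol(lmap)
  rgb_arr <- array(1, dim = c(ny, nx, 3))  # white background / membrane
  inc <- lmap > 0
  vv <- vals[lmap[inc]]
  ci <- pmin(pmax(round((vv - limits[1]) / diff(limits) * 254) + 1, 1), 255)
  col <- grDevices::col2rgb(pal[ci]) / 255
  for (ch in 1:3) {
    plane <- rgb_arr[, , ch]
    plane[inc] <- col[ch, ]
    if (!is.null(excluded_labels)) plane[excluded_labels > 0] <- 0.6
    rgb_arr[, , ch] <- plane
  }
  png::writePNG(rgb_arr, path)
  invisible(path)
}
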