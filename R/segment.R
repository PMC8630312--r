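#' Segmentation and inclusion-filter parameters
#'
#' Thresholds of the size/shape inclusion filter applied after
#' segmentation. Cells outside the area bounds, below the solidity minimum,
#' above the eccentricity maximum, or touching the image border (when
#' `border_exclusion` is on) are excluded from analysis but retained for
#' rendering in gray.
#'
#' @param min_area_um2,max_area_um2 Area bounds in square micrometres.
#' @param min_solidity Minimum area / convex-hull-area, in (0, 1].
#' @param max_eccentricity Maximum moment-ellipse eccentricity, in [0, 1).
#' @param border_exclusion Exclude cells touching the image border.
#' @param min_seed_px Minimum marker size in pixels for watershed seeding.
#' @export
segmentation_params <- function(min_area_um2 = 30, max_area_um2 = 1500,
                                min_solidity = 0.8, max_eccentricity = 0.95,
                                border_exclusion = TRUE, min_seed_px = 9) {
  stopifnot(min_area_um2 > 0, max_area_um2 > min_area_um2,
            min_solidity > 0, min_solidity <= 1,
            max_eccentricity >= 0, max_eccentricity < 1)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_solidity = min_solidity,
                 max_eccentricity = max_eccentricity,
                 border_exclusion = border_exclusion,
                 min_seed_px = min_seed_px),
            class = "segmentation_params")
}

#' Segment cells from a membrane-marker image
#'
#' Marker-controlled tessellation of a membrane-outlined monolayer: the
#' smoothed image is thresholded (Otsu) to find the bright membrane
#' skeleton, connected interior regions become markers, and markers are
#' propagated back across the membrane ridge so every pixel is assigned to
#' exactly one cell. The procedure is deterministic.
#'
#' @param membrane_image A [raster_image()] with bright cell boundaries.
#' @param params A [segmentation_params()] (only `min_seed_px` is used
#'   here; apply [filter_cells()] for the inclusion filter).
#' @param smooth_px Pre-threshold smoothing FWHM in pixels (default 2).
#' @return An integer label matrix (0 = unassigned, k >= 1 = cell k) with
#'   labels compacted to 1..N. A flat (contrast-free) image yields zero
#'   cells with a warning.
#' @export
segment_cells <- function(membrane_image, params = segmentation_params(),
                          smooth_px = 2) {
  stopifnot(is_raster_image(membrane_image))
  px <- membrane_image$pixels
  if (diff(range(px)) <= 0 || stats::sd(px) < 1e-12) {
    warning("flat image: no cells segmented")
    return(matrix(0L, nrow(px), ncol(px)))
  }
  sm <- norm01(sep_convolve_reflect(
    px, gaussian_kernel_1d(smooth_px / (2 * sqrt(2 * log(2))))))
  th <- EBImage::otsu(mat_to_eb(sm), range = c(0, 1))
  interior <- sm < th
  seeds <- EBImage::bwlabel(mat_to_eb(interior * 1))
  # drop markers below the minimum seed size (noise specks)
  sizes <- tabulate(as.integer(EBImage::imageData(seeds)))
  small <- which(sizes < params$min_seed_px)
  sd_ <- EBImage::imageData(seeds)
  sd_[sd_ %in% small] <- 0L
  if (all(sd_ == 0L)) {
    warning("no interior markers found: zero cells")
    return(matrix(0L, nrow(px), ncol(px)))
  }
  seeds <- EBImage::Image(sd_)
  lmap <- EBImage::propagate(mat_to_eb(sm), seeds, lambda = 1e-4)
  compact_labels(matrix(as.integer(eb_to_mat(lmap)), nrow(px), ncol(px)))
}

# Relabel a label matrix to contiguous 1..N (0 preserved).
compact_labels <- function(lab) {
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  if (length(ids) == 0L) return(lab)
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- seq_along(ids)
  matrix(lut[lab + 1L], nrow(lab), ncol(lab))
}

#' Apply the size/shape inclusion filter to a label map
#'
#' Removes cells outside the configured area/solidity/eccentricity bounds
#' and, optionally, cells touching the image border. Excluded cells are
#' reported by their original labels (so they can be rendered in gray);
#' retained labels are compacted to 1..N.
#'
#' @param lmap Integer label matrix from [segment_cells()].
#' @param params A [segmentation_params()].
#' @param pixel_size_um Micrometres per pixel.
#' @return List with `labels` (filtered, compacted label matrix),
#'   `excluded_ids` (original labels removed), `excluded_labels` (matrix
#'   of only the excluded cells, original labels), and `reasons` (named
#'   character vector per excluded id).
#' @export
filter_cells <- function(lmap, params, pixel_size_um) {
  stopifnot(inherits(params, "segmentation_params"))
  ids <- setdiff(sort(unique(as.vector(lmap))), 0L)
  if (length(ids) == 0L)
    return(list(labels = lmap, excluded_ids = integer(0),
                excluded_labels = lmap * 0L, reasons = character(0)))
  geom <- label_geometry(lmap)
  ps2 <- pixel_size_um^2
  reasons <- character(0)
  excl <- logical(length(ids))
  for (k in seq_along(ids)) {
    g <- geom[[k]]
    area_um2 <- g$area_px * ps2
    r <- NULL
    if (area_um2 < params$min_area_um2) r <- "area_below_min"
    else if (area_um2 > params$max_area_um2) r <- "area_above_max"
    else if (g$solidity < params$min_solidity) r <- "solidity_below_min"
    else if (g$eccentricity > params$max_eccentricity) r <- "eccentricity_above_max"
    else if (params$border_exclusion && g$touches_border) r <- "touches_border"
    if (!is.null(r)) { excl[k] <- TRUE; reasons[as.character(ids[k])] <- r }
  }
  excluded_ids <- ids[excl]
  excluded_labels <- lmap
  excluded_labels[!(lmap %in% excluded_ids)] <- 0L
  out <- lmap
  out[lmap %in% excluded_ids] <- 0L
  list(labels = compact_labels(out), excluded_ids = excluded_ids,
       excluded_labels = excluded_labels, reasons = reasons)
}

# Per-label geometry used by the filter and by shape_metrics.
label_geometry <- function(lmap) {
  ids <- setdiff(sort(unique(as.vector(lmap))), 0L)
  ny <- nrow(lmap); nx <- ncol(lmap)
  v <- as.vector(lmap)
  X <- rep(seq_len(nx) - 1, each = ny)
  Y <- rep(seq_len(ny) - 1, nx)
  keep <- v > 0
  sp <- split(seq_along(v)[keep], v[keep])
  crack <- crack_perimeter(lmap)
  lapply(seq_along(ids), function(k) {
    idx <- sp[[as.character(ids[k])]]
    xs <- X[idx]; ys <- Y[idx]
    n <- length(idx)
    cx <- mean(xs); cy <- mean(ys)
    # second central moments (+1/12 pixel-integration term)
    mxx <- sum((xs - cx)^2) / n + 1 / 12
    myy <- sum((ys - cy)^2) / n + 1 / 12
    mxy <- sum((xs - cx) * (ys - cy)) / n
    tr <- mxx + myy
    dd <- sqrt(max((mxx - myy)^2 + 4 * mxy^2, 0))
    l1 <- (tr + dd) / 2; l2 <- (tr - dd) / 2
    ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
    sol <- if (n < 3) 1 else {
      hull <- grDevices::chull(xs, ys)
      ha <- polygon_area(xs[hull], ys[hull]) + n * 0  # hull of pixel centres
      # add half-perimeter correction is omitted; clamp to [.,1]
      if (ha <= 0) 1 else min(n / ha, 1)
    }
    list(cell_id = ids[k], area_px = n, centroid_px = c(cx, cy),
         eccentricity = ecc, solidity = sol,
         perimeter_px = crack[ids[k]],
         touches_border = any(xs == 0 | ys == 0 | xs == nx - 1 | ys == ny - 1),
         degenerate = n < 4)
  })
}

# Crack (exposed pixel edge) perimeter per label. Exact for axis-aligned
# rectangles; overestimates smooth boundaries by up to 4/pi (documented).
crack_perimeter <- function(lmap) {
  ny <- nrow(lmap); nx <- ncol(lmap)
  n <- max(lmap)
  if (n == 0L) return(numeric(0))
  per <- numeric(n)
  edge_count <- function(a, b) {
    d <- a != b & a > 0
    tabulate(a[d], nbins = n)
  }
  z <- 0L
  per <- per + edge_count(lmap, cbind(lmap[, -1], z))       # right
  per <- per + edge_count(lmap, cbind(z, lmap[, -nx]))      # left
  per <- per + edge_count(lmap, rbind(lmap[-1, ], z))       # down
  per <- per + edge_count(lmap, rbind(z, lmap[-ny, ]))      # up
  per
}

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}
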