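# Per-cell cortical band and interior pixel indices. The band is the set of
# mask pixels within `band_px` of the cell boundary (the boundary between a
# cell and its neighbours, or the image edge); the interior is the rest of
# the mask. Shared between the analyzer and the synthetic painter: it is the
# package's definition of "cortical band".
cell_band_interior <- function(lmap, band_px) {
  ids <- setdiff(sort(unique(as.vector(lmap))), 0L)
  ny <- nrow(lmap); nx <- ncol(lmap)
  band_idx <- vector("list", max(lmap, 1L))
  interior_idx <- vector("list", max(lmap, 1L))
  for (id in ids) {
    w <- which(lmap == id)
    rs <- ((w - 1L) %% ny) + 1L
    cs <- ((w - 1L) %/% ny) + 1L
    r0 <- min(rs); r1 <- max(rs); c0 <- min(cs); c1 <- max(cs)
    # 1-px zero pad so the image border counts as boundary
    m <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)
    m[cbind(rs - r0 + 2L, cs - c0 + 2L)] <- 1
    d <- eb_to_mat(EBImage::distmap(mat_to_eb(m)))
    inb <- d > 0 & d <= band_px
    int <- d > band_px
    to_full <- function(sel) {
      rc <- which(sel, arr.ind = TRUE)
      (rc[, 1] + r0 - 2L) + (rc[, 2] + c0 - 3L) * ny
    }
    band_idx[[id]] <- to_full(inb)
    interior_idx[[id]] <- to_full(int)
  }
  list(ids = ids, band_idx = band_idx, interior_idx = interior_idx)
}

#' Cortical enrichment index per cell
#'
#' For a cortex/cytoplasm marker image (e.g. a GFP-myosin analogue) and a
#' cell label map, computes per cell the ratio of the mean intensity in the
#' membrane-adjacent band (within `band_width_um` of the cell boundary,
#' inside the cell) to the mean intensity in the remaining cell interior.
#' An index of 1 means no cortical enrichment. Being a ratio of means, the
#' index is invariant to global intensity gain. Cells whose interior is
#' empty after removing the band, or whose interior mean is zero, are
#' flagged undefined and skipped.
#'
#' @param image A [raster_image()] of the cortical marker.
#' @param lmap Integer label matrix (from [segment_cells()] or ground
#'   truth).
#' @param band_width_um Band width in micrometres (default 1.5).
#' @return A data frame: `cell_id`, `cortical_index`, `defined`,
#'   `band_width_um`.
#' @export
cortical_index <- function(image, lmap, band_width_um = 1.5) {
  stopifnot(is_raster_image(image), band_width_um > 0)
  if (!all(dim(image$pixels) == dim(lmap)))
    stop("image and label map must have identical shape")
  band_px <- band_width_um / image$pixel_size_um
  bi <- cell_band_interior(lmap, band_px)
  px <- image$pixels
  rows <- lapply(bi$ids, function(id) {
    b <- bi$band_idx[[id]]; itr <- bi$interior_idx[[id]]
    if (length(b) == 0L || length(itr) == 0L)
      return(data.frame(cell_id = id, cortical_index = NA_real_,
                        defined = FALSE, band_width_um = band_width_um))
    mi <- mean(px[itr])
    if (!is.finite(mi) || mi <= 0)
      return(data.frame(cell_id = id, cortical_index = NA_real_,
                        defined = FALSE, band_width_um = band_width_um))
    data.frame(cell_id = id, cortical_index = mean(px[b]) / mi,
               defined = TRUE, band_width_um = band_width_um)
  })
  do.call(rbind, rows)
}

#' Fraction of cells classified as cortical
#'
#' Binary per-cell classification (index at or above `threshold` = cortical)
#' and the percentage of classified-positive cells, the summary statistic
#' used to compare stretch conditions. Undefined-index cells are excluded
#' from the denominator and their count reported.
#'
#' @param results Data frame from [cortical_index()].
#' @param threshold Classification threshold on the index (default 1.5).
#' @return List with `fraction_pct` (percentage in [0, 100]), `n_cortical`,
#'   `n_defined`, `n_undefined`.
#' @export
fraction_cortical <- function(results, threshold = 1.5) {
  if (nrow(results) == 0L) stop("empty result set")
  def <- results[results$defined, , drop = FALSE]
  if (nrow(def) == 0L) stop("all cells have undefined cortical index")
  pos <- sum(def$cortical_index >= threshold)
  list(fraction_pct = 100 * pos / nrow(def),
       n_cortical = pos, n_defined = nrow(def),
       n_undefined = sum(!results$defined))
}
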