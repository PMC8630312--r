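# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# Small monolayer (192 px, ~20 cells) for registration/segmentation tests.
mono_small <- function() {
  fixture("mono_small", function()
    generate_monolayer(monolayer_spec(field_px = 192, seed = 5)))
}

# Translate an image by (dx, dy) px via bilinear resampling (edge clamp).
translate_image <- function(img, dx, dy) {
  px <- img$pixels
  ny <- nrow(px); nx <- ncol(px)
  Xp <- rep(seq_len(nx) - 1, each = ny)
  Yp <- rep(seq_len(ny) - 1, nx)
  out <- matrix(cellstrain:::bilinear_sample_clamp(px, Xp - dx, Yp - dy),
                ny, nx)
  raster_image(out, img$pixel_size_um, img$frame_interval_min)
}

# One-to-one IoU matching fraction between a ground-truth and predicted
# label map (best-overlap candidate per truth cell, greedy one-to-one).
iou_match_fraction <- function(truth, pred, min_iou = 0.7) {
  tab <- table(truth = as.vector(truth), pred = as.vector(pred))
  tt <- rowSums(tab); pp <- colSums(tab)
  truth_ids <- setdiff(rownames(tab), "0")
  used <- character(0)
  matched <- 0L
  for (i in truth_ids) {
    j <- names(which.max(tab[i, !colnames(tab) %in% c("0", used)]))
    if (length(j) == 0) next
    inter <- tab[i, j]
    if (inter / (tt[i] + pp[j] - inter) >= min_iou) {
      matched <- matched + 1L
      used <- c(used, j)
    }
  }
  matched / length(truth_ids)
}

# Rasterised disk / ellipse label images for shape oracles.
raster_disk <- function(r_px, size = 2L * r_px + 24L) {
  ctr <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), size)
  ys <- matrix(rep(0:(size - 1), size), size)
  m <- matrix(0L, size, size)
  m[(xs - ctr)^2 + (ys - ctr)^2 <= r_px^2] <- 1L
  m
}

raster_ellipse <- function(a_px, b_px, size = 2L * a_px + 16L) {
  ctr <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), size)  # x along columns
  ys <- matrix(rep(0:(size - 1), size), size)
  m <- matrix(0L, size, size)
  m[((xs - ctr) / a_px)^2 + ((ys - ctr) / b_px)^2 <= 1] <- 1L
  m
}
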