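test_that("synthetic monolayer cells are matched one-to-one at IoU >= 0.7", {
  mono <- mono_small()
  lmap <- segment_cells(preprocess_pair(mono$image, mono$image)$reference)
  expect_gte(iou_match_fraction(mono$labels, lmap), 0.95)
})

test_that("flat and structureless images yield zero cells with a warning", {
  flat <- raster_image(matrix(0, 64, 64), 0.5)
  expect_warning(lmap <- segment_cells(flat), "flat|no cells|markers")
  expect_equal(max(lmap), 0)
})

test_that("a single bright rectangle outline yields one cell, its interior", {
  px <- matrix(0, 64, 64)
  px[20:45, 15:50] <- 0   # interior
  px[20, 15:50] <- 100; px[45, 15:50] <- 100
  px[20:45, 15] <- 100; px[20:45, 50] <- 100
  lmap <- segment_cells(raster_image(px, 0.5), smooth_px = 1)
  # exactly one interior cell away from the image border region
  inner <- lmap[25:40, 20:45]
  expect_length(setdiff(unique(as.vector(inner)), 0L), 1L)
  id <- setdiff(unique(as.vector(inner)), 0L)
  area <- sum(lmap == id)
  expect_gte(area, 24 * 34 * 0.8)   # interior 24 x 34 px up to membrane share
  expect_lte(area, 26 * 36)
})

test_that("size threshold excludes small cells and reports reasons", {
  lmap <- matrix(0L, 40, 40)
  lmap[5:8, 5:8] <- 1L        # 16 px^2 -> 4 um^2 at 0.5 um/px
  lmap[20:35, 20:35] <- 2L    # 256 px^2 -> 64 um^2
  filt <- filter_cells(lmap, segmentation_params(min_area_um2 = 20,
                                                 border_exclusion = FALSE), 0.5)
  expect_equal(filt$excluded_ids, 1L)
  expect_equal(unname(filt$reasons["1"]), "area_below_min")
  expect_equal(max(filt$labels), 1L)   # compacted
})

test_that("border exclusion retains only interior cells", {
  # 5 cells: 2 touching the border
  lmap <- matrix(0L, 50, 50)
  lmap[1:10, 5:15] <- 1L           # touches top border
  lmap[15:24, 5:15] <- 2L
  lmap[28:37, 5:15] <- 3L
  lmap[15:24, 20:30] <- 4L
  lmap[41:50, 20:30] <- 5L         # touches bottom border
  p <- segmentation_params(min_area_um2 = 1, border_exclusion = TRUE)
  filt <- filter_cells(lmap, p, 0.5)
  expect_equal(length(filt$excluded_ids), 2L)
  expect_equal(max(filt$labels), 3L)
})

test_that("filtering is idempotent and retained cells partition pixels", {
  mono <- mono_small()
  lmap <- segment_cells(preprocess_pair(mono$image, mono$image)$reference)
  p <- segmentation_params()
  f1 <- filter_cells(lmap, p, mono$image$pixel_size_um)
  f2 <- filter_cells(f1$labels, p, mono$image$pixel_size_um)
  expect_identical(f1$labels, f2$labels)
  expect_length(f2$excluded_ids, 0L)
  # disjoint by construction of a label map; check labels are 1..N
  ids <- setdiff(sort(unique(as.vector(f1$labels))), 0L)
  expect_identical(ids, seq_along(ids))
})

test_that("segmentation is deterministic", {
  mono <- mono_small()
  ref <- preprocess_pair(mono$image, mono$image)$reference
  expect_identical(segment_cells(ref), segment_cells(ref))
})
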