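# Analytic displacement fields on the fixture's grid, bypassing image
# matching, to test the per-cell fit in isolation.
analytic_field <- function(lmap, fx, fy, step = 8) {
  n <- dim(lmap)
  gx <- seq(16, n[2] - 17, by = step) - 0.5
  gy <- seq(16, n[1] - 17, by = step) - 0.5
  X <- outer(rep(1, length(gy)), gx)
  Y <- outer(gy, rep(1, length(gx)))
  structure(list(x = gx, y = gy, u_x = fx(X, Y), u_y = fy(X, Y),
                 valid = matrix(TRUE, length(gy), length(gx))),
            class = "displacement_field")
}

test_that("per-cell strain is exact for zero, uniform and graded fields", {
  mono <- mono_small()
  lmap <- filter_cells(mono$labels, segmentation_params(),
                       mono$image$pixel_size_um)$labels
  zero <- per_cell_strain(analytic_field(lmap, function(x, y) 0 * x,
                                         function(x, y) 0 * x), lmap)
  expect_true(all(zero$included_flag))
  expect_equal(max(abs(c(zero$e_xx, zero$e_yy, zero$e_xy))), 0)

  unif <- per_cell_strain(analytic_field(lmap,
                                         function(x, y) 0.15 * x,
                                         function(x, y) 0 * x), lmap)
  expect_lt(max(abs(unif$e_xx - 0.15)), 0.005)
  expect_lt(max(abs(unif$e_yy)), 1e-10)

  n <- dim(lmap)
  grad <- per_cell_strain(analytic_field(lmap,
    function(x, y) 0.10 * x^2 / (2 * (n[2] - 1)),
    function(x, y) 0 * x), lmap)
  cen <- shape_metrics(lmap, 1)
  truth <- 0.10 * cen$centroid_x_um / (n[2] - 1)
  expect_lt(max(abs(grad$e_xx - truth[match(grad$cell_id, cen$cell_id)])),
            0.01)
})

test_that("cells with too few displacement samples are flagged, not dropped", {
  lmap <- matrix(0L, 64, 64)
  lmap[30:33, 30:33] <- 1L   # 4x4 cell: one grid point at step 8
  fld <- analytic_field(lmap, function(x, y) 0 * x, function(x, y) 0 * x)
  rec <- per_cell_strain(fld, lmap)
  expect_equal(nrow(rec), 1L)
  expect_false(rec$included_flag)
  expect_match(rec$exclude_reason, "insufficient")
  expect_equal(nrow(per_cell_strain(fld, lmap * 0L)), 0L)
})

test_that("shape metrics match analytic disk, ellipse and square", {
  disk <- shape_metrics(raster_disk(20), 1)
  expect_lt(abs(disk$area_um2 - pi * 400) / (pi * 400), 0.02)
  expect_lt(disk$eccentricity, 0.1)

  ell <- shape_metrics(raster_ellipse(40, 20), 1)
  expect_lt(abs(ell$eccentricity - sqrt(0.75)), 0.02)

  sq <- matrix(0L, 30, 30); sq[6:25, 6:25] <- 1L
  sm <- shape_metrics(sq, 1)
  expect_equal(sm$area_um2, 400)
  expect_lt(abs(sm$perimeter_um - 80) / 80, 0.05)

  single <- matrix(0L, 8, 8); single[4, 4] <- 1L
  expect_true(shape_metrics(single, 1)$degenerate)
})

test_that("shape changes are zero for identical frames and track stretch", {
  mono <- mono_small()
  lmap <- filter_cells(mono$labels, segmentation_params(),
                       mono$image$pixel_size_um)$labels
  sm <- shape_metrics(lmap, 0.5)
  same <- shape_change(sm, sm)
  expect_equal(max(abs(same$per_cell$area_pct)), 0)
  expect_equal(same$summary$mean_pct, c(0, 0, 0))

  # pure translation: metrics invariant within resampling noise
  Ttr <- affine2d(t = c(6.3, -4.2))
  sm_tr <- shape_metrics(map_labels(lmap, Ttr, expand = TRUE), 0.5)
  tr <- shape_change(sm, sm_tr)
  expect_lt(max(abs(tr$summary$mean_pct[1:2])), 1)

  # 15% x-stretch: area scales by 1.15
  Tst <- affine2d(matrix(c(1.15, 0, 0, 1), 2))
  sm_st <- shape_metrics(map_labels(lmap, Tst, expand = TRUE), 0.5)
  st <- shape_change(sm, sm_st)
  expect_lt(abs(st$summary$mean_pct[st$summary$metric == "area"] - 15), 0.5)
})

test_that("mean per-cell area change is consistent with the strain tensor", {
  # (1+e_xx)(1+e_yy) - 1 vs area change, across stretches up to 20%
  mono <- mono_small()
  lmap <- filter_cells(mono$labels, segmentation_params(),
                       mono$image$pixel_size_um)$labels
  sm <- shape_metrics(lmap, 0.5)
  for (e in c(0.10, 0.20)) {
    Tst <- affine2d(matrix(c(1 + e, 0, 0, 1), 2))
    sm_d <- shape_metrics(map_labels(lmap, Tst, expand = TRUE), 0.5)
    ch <- shape_change(sm, sm_d)
    expect_lt(abs(ch$summary$mean_pct[ch$summary$metric == "area"] - 100 * e),
              1)
  }
})

test_that("strain overlay rendering writes a PNG of the field size", {
  mono <- mono_small()
  lmap <- filter_cells(mono$labels, segmentation_params(),
                       mono$image$pixel_size_um)$labels
  rec <- data.frame(cell_id = seq_len(max(lmap)),
                    e_xx = seq(0.1, 0.2, length.out = max(lmap)))
  path <- withr::local_tempfile(fileext = ".png")
  plot_strain_map(lmap, rec, "e_xx", path)
  arr <- png::readPNG(path)
  expect_equal(dim(arr)[1:2], dim(lmap))
})
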