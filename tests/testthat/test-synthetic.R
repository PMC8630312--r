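test_that("cell count tracks the requested density within 10%", {
  spec <- monolayer_spec(field_px = 512, pixel_size_um = 0.5,
                         density_cells_per_mm2 = 2200, seed = 42)
  mono <- generate_monolayer(spec)
  target <- 2200 * (512 * 0.5)^2 / 1e6
  n <- length(setdiff(unique(as.vector(mono$labels)), 0L))
  expect_lt(abs(n - target) / target, 0.10)
})

test_that("generation is bitwise reproducible and respects noise settings", {
  spec <- monolayer_spec(field_px = 128, seed = 3)
  m1 <- generate_monolayer(spec)
  m2 <- generate_monolayer(spec)
  expect_identical(m1$image$pixels, m2$image$pixels)
  expect_identical(m1$labels, m2$labels)

  clean <- monolayer_spec(field_px = 128, seed = 3, noise_sd = 0,
                          speckle_amp = 0)
  mc <- generate_monolayer(clean)
  expect_setequal(unique(as.vector(mc$image$pixels)), c(40, 200))
})

test_that("spec validation rejects impossible densities", {
  expect_error(monolayer_spec(field_px = 64, pixel_size_um = 10,
                              density_cells_per_mm2 = 1e6), "4 px")
})

test_that("uniform deformation carries exact per-cell truth", {
  spec <- monolayer_spec(field_px = 128, seed = 3)
  mono <- generate_monolayer(spec)
  def <- apply_deformation(mono$image, mono$labels,
                           deformation_spec("uniform", e_xx = 0.15))
  expect_true(all(def$truth$e_xx == 0.15))
  expect_true(all(def$truth$e_yy == 0))

  ident <- apply_deformation(mono$image, mono$labels,
                             deformation_spec("uniform"))
  expect_true(all(ident$truth$e_xx == 0))
  expect_lt(mean(abs(ident$image$pixels - mono$image$pixels)),
            1e-8 * mean(mono$image$pixels))
  expect_error(apply_deformation(mono$image, mono$labels,
                                 deformation_spec("uniform", e_xx = -1.2)),
               "fold")
})

test_that("graded deformation truth equals the gradient at each centroid", {
  spec <- monolayer_spec(field_px = 128, seed = 3)
  mono <- generate_monolayer(spec)
  def <- apply_deformation(mono$image, mono$labels,
                           deformation_spec("graded", e_xx_range = c(0, 0.1)))
  cen <- cellstrain:::cell_centroids(mono$labels)
  expect_equal(def$truth$e_xx, 0.1 * cen$x_px / (ncol(mono$labels) - 1))
  # inverse map is the exact inverse of the forward map
  xs <- seq(0, 127, by = 0.5)
  fwd <- cellstrain:::graded_forward_x(xs, 0, 0.1, 127)
  expect_equal(cellstrain:::graded_inverse_x(fwd, 0, 0.1, 127), xs,
               tolerance = 1e-9)
})

test_that("ramp mode yields one deformed image and truth table per step", {
  spec <- monolayer_spec(field_px = 128, seed = 3)
  mono <- generate_monolayer(spec)
  ramp <- apply_deformation(mono$image, mono$labels,
                            deformation_spec("ramp", steps = c(0.02, 0.04)))
  expect_length(ramp, 2L)
  expect_true(all(ramp[[2]]$truth$e_xx == 0.04))
})

test_that("time-lapse drift follows the programmed schedule exactly", {
  spec <- monolayer_spec(field_px = 96, seed = 3)
  tl <- generate_timelapse(spec, c(12, 9.6), frame_interval_min = 10)
  expect_length(tl$frames, 13L)
  # 12 um/h at 0.5 um/px and 10-min frames -> 4 px per frame
  expect_equal(tl$truth$speed_um_h, rep(c(12, 9.6), each = 6))
  shift_px <- tl$truth$speed_um_h / 6 / spec$pixel_size_um
  expect_equal(shift_px[1], 4)

  still <- generate_timelapse(monolayer_spec(field_px = 96, seed = 3,
                                             noise_sd = 0), c(0, 0),
                              frame_noise_sd = 0)
  expect_identical(still$frames[[1]]$pixels, still$frames[[13]]$pixels)
})

test_that("cortical fixture flags exactly the programmed fraction", {
  spec <- monolayer_spec(field_px = 192, seed = 23)
  cor <- generate_cortical(spec, 0.4, 2)
  n <- nrow(cor$truth)
  expect_equal(sum(cor$truth$cortical), round(0.4 * n))
  none <- generate_cortical(spec, 0, 2)
  expect_equal(sum(none$truth$cortical), 0L)
})

test_that("an undeformed pair passes end-to-end with near-zero strain", {
  mono <- mono_small()
  res <- run_strain(mono$image, mono$image)
  inc <- res$records$included_flag
  e <- abs(cbind(res$records$e_xx, res$records$e_yy,
                 res$records$e_xy)[inc, ])
  expect_gte(mean(apply(e, 1, max) < 0.005), 0.95)
})
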