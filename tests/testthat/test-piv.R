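piv_frames <- function() {
  fixture("piv_frames", function() {
    mono <- generate_monolayer(monolayer_spec(field_px = 256, seed = 13))
    raster_image(mono$image$pixels, 1, 10)  # 1 um/px, 10 min frames
  })
}

test_that("identical frames give a sub-0.05 px noise floor", {
  a <- piv_frames()
  vf <- piv_pair(a, a)
  px_per_frame <- sqrt(vf$v_x^2 + vf$v_y^2) / (1 * 6)  # um/h -> px/frame
  expect_true(any(vf$valid))
  expect_lt(max(px_per_frame[vf$valid]), 0.05)
})

test_that("a uniform 3 px shift is recovered as 18 um/h", {
  a <- piv_frames()
  b <- translate_image(a, 3, 0)
  vf <- piv_pair(a, b)
  expect_lt(max(abs(vf$v_x[vf$valid] / 6 - 3)), 0.2)  # px units
  expect_lt(abs(mean(vf$v_x[vf$valid]) - 18), 1.2)
  expect_lt(max(abs(vf$v_y[vf$valid])), 1.2)
})

test_that("velocities are translation-equivariant and gain-invariant", {
  a <- piv_frames()
  b <- translate_image(a, 1.6, 0.8)
  v1 <- piv_pair(a, b)
  b2 <- translate_image(a, 4.6, 0.8)   # extra (3, 0) px shift
  v2 <- piv_pair(a, b2)
  both <- v1$valid & v2$valid
  expect_lt(max(abs((v2$v_x - v1$v_x)[both] / 6 - 3)), 0.2)

  a_g <- raster_image(a$pixels * 2.7, 1, 10)
  b_g <- raster_image(b$pixels * 2.7, 1, 10)
  v3 <- piv_pair(a_g, b_g)
  expect_equal(v3$v_x[v3$valid & v1$valid], v1$v_x[v3$valid & v1$valid],
               tolerance = 1e-9)
})

test_that("50% overlap yields grid spacing of half a window", {
  a <- piv_frames()
  vf <- piv_pair(a, a, window = c(96, 48), overlap_fraction = 0.5)
  expect_equal(unique(diff(vf$x)), 48)
  expect_equal(unique(diff(vf$y)), 24)
  expect_error(piv_pair(a, a, window = c(512, 48)), "larger than image")
})

test_that("hourly aggregation averages fields and drops partial hours", {
  mk <- function(speed) {
    structure(list(x = 1, y = 1,
                   v_x = matrix(speed, 2, 2), v_y = matrix(0, 2, 2),
                   valid = matrix(TRUE, 2, 2), snr = matrix(Inf, 2, 2),
                   pixel_size_um = 1, frame_interval_min = 10),
              class = "velocity_field")
  }
  s <- mean_speed_per_hour(replicate(6, mk(10), simplify = FALSE))
  expect_equal(s$mean_speed_um_h, 10)
  expect_equal(s$sd_um_h, 0)
  expect_equal(s$n_fields, 6L)

  fields <- c(replicate(6, mk(12), simplify = FALSE),
              replicate(6, mk(8), simplify = FALSE))
  s2 <- mean_speed_per_hour(fields)
  expect_equal(s2$mean_speed_um_h, c(12, 8))

  expect_warning(s3 <- mean_speed_per_hour(c(fields, list(mk(5)))),
                 "partial")
  expect_equal(nrow(s3), 2L)
  expect_error(mean_speed_per_hour(list()), "no velocity fields")
})

test_that("normalization divides by the baseline bin", {
  s <- structure(data.frame(hour = 1:3, mean_speed_um_h = c(10, 8, 9),
                            sd_um_h = 0, n_fields = 6L),
                 class = c("speed_series", "data.frame"))
  expect_equal(normalize_speeds(s)$normalized_speed, c(1, 0.8, 0.9))
  s$mean_speed_um_h <- c(7, 7, 7)
  expect_equal(normalize_speeds(s)$normalized_speed, c(1, 1, 1))
  s$mean_speed_um_h[1] <- 0
  expect_error(normalize_speeds(s), "baseline")
})

test_that("a programmed drift movie yields the scheduled hourly speeds", {
  spec <- monolayer_spec(field_px = 192, seed = 17)
  tl <- generate_timelapse(spec, c(11, 9))
  fields <- lapply(seq_len(length(tl$frames) - 1), function(k)
    piv_pair(tl$frames[[k]], tl$frames[[k + 1]], window = c(96, 48)))
  s <- mean_speed_per_hour(fields)
  expect_equal(s$mean_speed_um_h, c(11, 9), tolerance = 0.1)
})
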