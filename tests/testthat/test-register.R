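test_that("affine transforms validate, apply, invert and compose", {
  T1 <- affine2d(matrix(c(1.1, 0, 0, 0.95), 2), c(3, -2))
  xy <- cbind(c(0, 10), c(0, 20))
  expect_equal(affine_apply(T1, xy),
               cbind(c(3, 14), c(-2, 17)))
  rt <- affine_compose(affine_invert(T1), T1)
  expect_equal(rt$A, diag(2), tolerance = 1e-12)
  expect_equal(rt$t, c(0, 0), tolerance = 1e-12)
  expect_error(affine2d(matrix(c(-1, 0, 0, 1), 2)), "orientation")
})

test_that("affine_to_strain matches closed forms and is linear in A - I", {
  expect_equal(unlist(affine_to_strain(affine2d())[c("e_xx", "e_yy", "e_xy")]),
               c(e_xx = 0, e_yy = 0, e_xy = 0))
  sc <- affine_to_strain(affine2d(matrix(c(1.15, 0, 0, 1), 2)))
  expect_equal(sc$e_xx, 0.15)
  expect_equal(sc$e_yy, 0)
  expect_equal(sc$e_xy, 0)
  th <- 0.10
  rot <- affine_to_strain(affine2d(matrix(c(cos(th), sin(th),
                                            -sin(th), cos(th)), 2)))
  expect_equal(rot$e_xy, 0)
  expect_equal(rot$e_xx, cos(th) - 1, tolerance = 1e-12)
  expect_equal(rot$e_yy, cos(th) - 1, tolerance = 1e-12)

  # linearity: strain of blended transform = blend of strains
  A1 <- matrix(c(1.12, 0.01, 0.03, 0.97), 2)
  A2 <- matrix(c(1.02, -0.02, 0.01, 1.05), 2)
  for (w in c(0.25, 0.5)) {
    blend <- affine_to_strain(affine2d(w * A1 + (1 - w) * A2))
    s1 <- affine_to_strain(affine2d(A1)); s2 <- affine_to_strain(affine2d(A2))
    for (cmp in c("e_xx", "e_yy", "e_xy"))
      expect_equal(blend[[cmp]], w * s1[[cmp]] + (1 - w) * s2[[cmp]],
                   tolerance = 1e-12)
  }
})

test_that("self-registration returns the identity", {
  mono <- mono_small()
  pair <- preprocess_pair(mono$image, mono$image)
  reg <- register_affine(pair$reference, pair$deformed)
  expect_lt(max(abs(reg$transform$A - diag(2))), 1e-3)
  expect_lt(sqrt(sum(reg$transform$t^2)), 0.1)
})

test_that("known translations and scalings are recovered", {
  mono <- mono_small()
  def_t <- translate_image(mono$image, 5, 3)
  pair <- preprocess_pair(mono$image, def_t)
  reg <- register_affine(pair$reference, pair$deformed)
  expect_lt(max(abs(reg$transform$t - c(5, 3))), 0.2)

  def_s <- apply_deformation(mono$image, mono$labels,
                             deformation_spec("uniform", e_xx = 0.15))$image
  pair <- preprocess_pair(mono$image, def_s)
  reg <- register_affine(pair$reference, pair$deformed)
  expect_lt(abs(reg$transform$A[1, 1] - 1.15), 0.005)
  expect_lt(abs(reg$transform$A[2, 2] - 1), 0.005)
})

test_that("forward and backward registrations are inverse-consistent", {
  mono <- mono_small()
  def <- apply_deformation(mono$image, mono$labels,
                           deformation_spec("uniform", e_xx = 0.10))$image
  pair <- preprocess_pair(mono$image, def)
  fwd <- register_affine(pair$reference, pair$deformed)$transform
  bwd <- register_affine(pair$deformed, pair$reference)$transform
  comp <- affine_compose(bwd, fwd)
  n <- dim(mono$image$pixels)
  corners <- cbind(c(0, n[2] - 1, 0, n[2] - 1), c(0, 0, n[1] - 1, n[1] - 1))
  moved <- affine_apply(comp, corners)
  expect_lt(max(sqrt(rowSums((moved - corners)^2))), 0.5)
})

test_that("dense displacement recovers uniform and graded fields", {
  mono <- mono_small()
  pair <- preprocess_pair(mono$image, mono$image)
  fld <- dense_displacement(pair$reference, pair$deformed, affine2d())
  expect_lt(max(abs(c(fld$u_x[fld$valid], fld$u_y[fld$valid]))), 0.1)

  def_t <- translate_image(mono$image, 4, 0)
  pair <- preprocess_pair(mono$image, def_t)
  fld <- dense_displacement(pair$reference, pair$deformed,
                            affine2d(t = c(4, 0)))
  expect_lt(max(abs(fld$u_x[fld$valid] - 4)), 0.2)
  expect_lt(max(abs(fld$u_y[fld$valid])), 0.2)

  expect_error(dense_displacement(pair$reference, pair$deformed,
                                  affine2d(), block_px = 8), ">= 16")
})

test_that("strain recovery is strictly monotone across imposed scales", {
  mono <- mono_small()
  rec <- vapply(c(0, 0.05, 0.10, 0.15, 0.20), function(e) {
    def <- apply_deformation(mono$image, mono$labels,
                             deformation_spec("uniform", e_xx = e))$image
    pair <- preprocess_pair(mono$image, def)
    affine_to_strain(register_affine(pair$reference,
                                     pair$deformed)$transform)$e_xx
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_lt(max(abs(rec - c(0, 0.05, 0.10, 0.15, 0.20))), 0.005)
})

test_that("registration failure raises an error rather than an identity", {
  # two unrelated random fields: metric cannot improve; either a failure
  # error or a near-identity result with a tiny metric is acceptable, but
  # an out-of-bounds transform must never be returned silently
  set.seed(9)
  a <- raster_image(matrix(runif(96 * 96), 96), 0.5)
  flat <- raster_image(matrix(1, 96, 96) + 0, 0.5)
  expect_error(
    suppressWarnings(register_affine(a, flat)),
    "registration failure|bounds|metric", ignore.case = TRUE)
})
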