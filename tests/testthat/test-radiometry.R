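make_cube <- function(vals, B = length(vals)) {
  # 2x2 cube with constant value per band
  array(rep(vals, each = 4), dim = c(2, 2, B))
}

test_that("DN to radiance applies gain after dark subtraction", {
  cfg <- radiometric_config(gain = rep(0.5, 3), dark = rep(10, 3))
  L <- dn_to_radiance(make_cube(c(110, 110, 110)), cfg)
  expect_equal(unique(as.vector(L)), 50)
  # dark-only signal is zero
  L0 <- dn_to_radiance(make_cube(c(10, 10, 10)), cfg)
  expect_equal(unique(as.vector(L0)), 0)
  # identity sensor
  cfg1 <- radiometric_config(gain = rep(1, 3), dark = rep(0, 3))
  expect_equal(unique(as.vector(dn_to_radiance(make_cube(rep(100, 3)),
                                               cfg1))), 100)
})

test_that("negative radiance is preserved and reported, shapes checked", {
  cfg <- radiometric_config(gain = rep(1, 3), dark = rep(50, 3))
  L <- dn_to_radiance(make_cube(c(40, 60, 40)), cfg)
  expect_equal(attr(L, "negative_fraction"), 2 / 3, tolerance = 1e-12)
  expect_true(any(L < 0))
  expect_error(dn_to_radiance(make_cube(rep(1, 4)), cfg),
               class = "shape_error")
})

test_that("the empirical line interpolates two panels exactly", {
  # radiances 10 -> 0.1 and 30 -> 0.5: slope 0.02, intercept -0.1
  co <- fit_elm(matrix(c(10, 30), 2, 1), c(0.1, 0.5))
  expect_equal(co$slope, 0.02)
  expect_equal(co$intercept, -0.1)
  expect_equal(co$rms, 0)
  # identity: radiances equal reflectances
  co2 <- fit_elm(matrix(c(0.02, 0.09, 0.25, 0.5, 0.88), 5, 1),
                 c(0.02, 0.09, 0.25, 0.5, 0.88))
  expect_equal(co2$slope, 1)
  expect_equal(co2$intercept, 0, tolerance = 1e-12)
})

test_that("degenerate panel sets are rejected with the band named", {
  expect_error(fit_elm(matrix(1, 1, 3), 0.5), class = "degenerate_fit")
  err <- tryCatch(fit_elm(matrix(c(1, 1, 1, 2), 2, 2), c(0.1, 0.5)),
                  error = identity)
  expect_s3_class(err, "degenerate_fit")
  expect_match(conditionMessage(err), "band 1")
})

test_that("apply_elm maps affinely, clips on request, checks shapes", {
  co <- data.frame(band = 1, slope = 0.02, intercept = -0.1, rms = 0)
  cube <- array(30, dim = c(2, 2, 1))
  expect_equal(unique(as.vector(apply_elm(cube, co))), 0.5)
  id <- data.frame(band = 1:3, slope = 1, intercept = 0, rms = 0)
  cube3 <- make_cube(c(0.2, -0.1, 1.4))
  expect_equal(apply_elm(cube3, id), cube3, ignore_attr = TRUE)
  clipped <- apply_elm(cube3, id, clip_policy = "unit")
  expect_equal(range(clipped), c(0, 1))
  expect_equal(attr(clipped, "clipped_fraction"), 2 / 3, tolerance = 1e-12)
  expect_error(apply_elm(cube3, co), class = "shape_error")
})

test_that("apply_elm preserves pixel ordering for positive slopes", {
  set.seed(1)
  cube <- array(runif(5 * 5 * 2), dim = c(5, 5, 2))
  co <- data.frame(band = 1:2, slope = c(0.3, 2), intercept = c(-0.1, 0.4),
                   rms = 0)
  out <- apply_elm(cube, co)
  for (b in 1:2)
    expect_identical(order(out[, , b]), order(cube[, , b]))
})

test_that("noise-free synthetic scene round-trips through the ELM exactly", {
  fx <- test_scene()
  cal <- calibrate_scene(fx$scene)
  # panels recover their nominal reflectances
  pan <- panel_mean_radiance(cal$radiance, fx$scene$panel_specs,
                             fx$scene$gsd, fx$layout$extent_y)
  recovered <- t(apply(pan$radiance, 1, function(L)
    cal$coeffs$slope * L + cal$coeffs$intercept))
  expect_lt(max(abs(recovered - pan$reflectance)), 1e-8)
  # every pixel of the scene recovers truth
  expect_lt(max(abs(cal$reflectance - fx$scene$reflectance_truth)), 1e-6)
})
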