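# Golden values frozen at first release on the reference spectrum.
golden_vi <- c(
  NDVI1 = 0.781132896736, NDVI2 = 0.781126897608, NDVI3 = 0.781132896736,
  GNDVI1 = 0.688033303633, GNDVI2 = 0.665608567282, SAVI = 0.588680967626,
  RENDVI = 0.731160439577, NDRE = 0.0134602834388, NRER = 1.92005356891,
  TCARI = 0.143167413097, MTVI1 = 0.611441013876, MTVI2 = 0.606880271072,
  EVI = 3.46296947861, LCI = 0.428666961832, MTCIvar = 3.03659490108,
  NRI = -0.0238847599429, PRI = -0.0660083211955, SPVI = 0.57142078177,
  SR710 = 1.91028001459, SR680 = 6.43540135046, RVI = 8.13545958512,
  VOG1 = 1.42503693136, GM = 4.82608272036, MNDm = 0.541347946371,
  NDRE2 = 0.208563205207, MCARI2 = 0.0879627403556, TVI = 23.5982173183,
  EVI2 = 3.2611940489, REP = 699.951107129, maxR = 0.00166100919034,
  sumR = 0.00302131187991, maxRE = 0.00473889049583,
  sumRE = 0.00473889049583, maxLARE = 0.00670045832745,
  sumLARE = 0.0114393488233, maxNIR = 5.00835954005e-05,
  sumNIR = 9.98815968015e-05)

test_that("the registry covers every printed row exactly once", {
  reg <- vi_registry()
  expect_equal(nrow(reg), 37)  # 38 printed rows; the repeated row collapses
  expect_setequal(reg$name, names(golden_vi))
  expect_true(reg$printed_twice[reg$name == "NRER"])
  expect_equal(sum(reg$printed_twice), 1)
  expect_equal(sum(reg$uses_derivative), 8)
  # identical printed formulas stay identical
  expect_identical(reg$formula[reg$name == "NDVI1"],
                   reg$formula[reg$name == "NDVI3"])
})

test_that("all indices reproduce their frozen golden values", {
  vi <- compute_indices_matrix(rbind(reference_spectrum()), default_grid)
  expect_equal(vi[1, names(golden_vi)], golden_vi, tolerance = 1e-10)
})

test_that("hand-computed values match the printed formulas", {
  # SAVI with R802 = 0.4, R660 = 0.1 -> 1.5 * 0.3 / 1.0 = 0.45
  s <- spectrum_with(list(`802` = 0.4, `660` = 0.1), base = 0.2)
  expect_equal(compute_index("SAVI", s, default_grid), 0.45,
               ignore_attr = TRUE)
  # two-band line: NDVI with equal bands is zero
  s2 <- spectrum_with(list(`850` = 0.3, `660` = 0.3))
  expect_equal(compute_index("NDVI1", s2, default_grid), 0,
               ignore_attr = TRUE)
  # REP printed structure: 700 + (45*R670 + R778)/2 - R850/(R735 - R695)
  s3 <- spectrum_with(list(`670` = 0.1, `778` = 0.5, `850` = 0.45,
                           `735` = 0.4, `695` = 0.2), base = 0.3)
  expect_equal(compute_index("REP", s3, default_grid),
               700 + (45 * 0.1 + 0.5) / 2 - 0.45 / (0.4 - 0.2),
               ignore_attr = TRUE)
})

test_that("NDVI1 and NDVI3 are identical on any spectrum", {
  set.seed(11)
  X <- matrix(runif(20 * 50, 0.01, 0.9), 20, 50)
  vi <- compute_indices_matrix(X, default_grid)
  expect_identical(vi[, "NDVI1"], vi[, "NDVI3"])
})

test_that("derivative indices vanish on constant spectra", {
  vi <- suppressWarnings(
    compute_indices_matrix(rbind(rep(0.3, 50)), default_grid))
  dhvi <- vi_registry()$name[vi_registry()$uses_derivative]
  expect_equal(unname(vi[1, dhvi]), rep(0, 8))
})

test_that("normalized differences stay inside (-1, 1); ratios positive", {
  set.seed(12)
  X <- matrix(runif(50 * 50, 0.001, 0.999), 50, 50)
  vi <- compute_indices_matrix(X, default_grid)
  nd <- c("NDVI1", "NDVI2", "NDVI3", "GNDVI1", "GNDVI2", "RENDVI", "NDRE",
          "NRI", "PRI", "NDRE2")
  expect_true(all(abs(vi[, nd]) < 1))
  expect_true(all(vi[, c("RVI", "SR680", "SR710", "VOG1", "GM")] > 0))
})

test_that("scale invariance holds exactly where the formulas imply it", {
  s <- reference_spectrum()
  v1 <- compute_indices_matrix(rbind(s), default_grid)[1, ]
  v2 <- compute_indices_matrix(rbind(3 * s), default_grid)[1, ]
  invariant <- c("NDVI1", "NDVI2", "NDVI3", "GNDVI1", "GNDVI2", "RENDVI",
                 "NDRE", "NRER", "MTCIvar", "NRI", "PRI", "SR710", "SR680",
                 "RVI", "VOG1", "GM", "MNDm", "NDRE2", "LCI", "EVI", "EVI2")
  not_invariant <- c("SAVI", "TCARI", "MTVI1", "MTVI2", "SPVI", "MCARI2",
                     "TVI", "REP", "maxR", "sumR", "maxRE", "sumRE",
                     "maxLARE", "sumLARE", "maxNIR", "sumNIR")
  expect_equal(v2[invariant], v1[invariant], tolerance = 1e-12)
  expect_true(all(abs(v2[not_invariant] - v1[not_invariant]) > 1e-8))
})

test_that("the first derivative matches closed forms", {
  g <- default_grid
  expect_equal(first_derivative(rep(0.4, 50), g), rep(0, 50))
  ramp <- 0.001 * g$centers
  expect_equal(first_derivative(ramp, g), rep(0.001, 50))
  expect_error(first_derivative(c(1, 2), make_band_grid(2, 500, 900)),
               class = "size_error")
})

test_that("zero denominators yield NA with a warning, never a crash", {
  s <- rep(0.3, 50)  # constant: MNDm and REP denominators are zero
  expect_warning(v <- compute_index("MNDm", s, default_grid), "undefined")
  expect_true(is.na(v))
  expect_warning(compute_index("REP", s, default_grid), "undefined")
})

test_that("window and pair dHVI modes differ only when extra bands fall in", {
  s <- reference_spectrum()
  # [690, 710] holds three grid bands: window sum > pair sum of endpoints
  w <- compute_index("sumLARE", s, default_grid, dhvi_mode = "window")
  p <- compute_index("sumLARE", s, default_grid, dhvi_mode = "pair")
  expect_gt(w, p)
})

test_that("aggregation modes agree on a uniform field and differ on mixes", {
  fx <- test_scene()
  sc <- fx$scene
  rois <- make_vine_rois(sc)[1:4, ]
  mask <- sc$class_mask == attr(sc$class_mask, "classes")[["canopy"]]
  uni <- array(rep(reference_spectrum(), each = prod(dim(mask))),
               dim = c(dim(mask), 50))
  a <- compute_all_indices(uni, fx$grid, mask, rois, sc$gsd,
                           fx$layout$extent_y, aggregation = "index-mean")
  b <- compute_all_indices(uni, fx$grid, mask, rois, sc$gsd,
                           fx$layout$extent_y, aggregation = "spectrum-mean")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the 60-vine dataset yields one row per vine, one col per index", {
  tr <- sample_traits(default_trait_spec(), 60, seed = 6)
  ds <- canopy_reflectance(tr, default_grid, seed = 6)
  vi <- compute_all_indices(ds)
  expect_equal(dim(vi), c(60, 1 + nrow(vi_registry())))
})
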