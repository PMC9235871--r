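# Brute-force moving-window percentile oracle (quadratic, small rasters only).
brute_percentile <- function(m, window_px, prob) {
  h <- window_px %/% 2
  out <- m
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    rr <- max(1, r - h):min(nrow(m), r + h)
    cc <- max(1, c - h):min(ncol(m), c + h)
    out[r, c] <- quantile(m[rr, cc], prob, names = FALSE, type = 7)
  }
  out
}

test_that("flat terrain gives an identically zero CHM", {
  dsm <- matrix(100, 30, 40)
  cfg <- segmentation_config(ground_window = 0.4, stride = 1)
  res <- compute_chm(dsm, gsd = 0.05, cfg)
  expect_equal(res$chm, matrix(0, 30, 40))
})

test_that("a constant offset is absorbed by the percentile ground model", {
  set.seed(3)
  ground <- matrix(100 + cumsum(rnorm(40, 0, 0.001)), 30, 40, byrow = TRUE)
  dsm <- ground + 0.5
  cfg <- segmentation_config(ground_window = 0.6, ground_percentile = 5,
                             stride = 1)
  res <- compute_chm(dsm, gsd = 0.05, cfg)
  oracle <- brute_percentile(dsm, round(0.6 / 0.05), 0.05)
  expect_equal(res$ground, oracle)
  # percentile surface tracks the offset ground, so the CHM is ~flat
  expect_lt(max(res$chm), 0.01)
})

test_that("strided evaluation matches the exact window on smooth ground", {
  set.seed(4)
  dsm <- matrix(100, 40, 50) + outer(seq(0, 0.2, length.out = 40),
                                     seq(0, 0.1, length.out = 50), `+`)
  exact <- compute_chm(dsm, 0.05, segmentation_config(ground_window = 0.5,
                                                      stride = 1))
  strided <- compute_chm(dsm, 0.05, segmentation_config(ground_window = 0.5,
                                                        stride = 4))
  expect_equal(strided$ground, exact$ground, tolerance = 1e-3)
})

test_that("canopy strips produce their height in the CHM", {
  fx <- test_scene()
  sc <- fx$scene
  res <- compute_chm(sc$dsm, sc$gsd, segmentation_config())
  classes <- attr(sc$class_mask, "classes")
  canopy <- sc$class_mask == classes[["canopy"]]
  expect_equal(mean(res$chm[canopy]), fx$layout$canopy_height,
               tolerance = 0.05)
  expect_lt(max(res$chm[!canopy]), 0.05)
})

test_that("window larger than the raster is a config error", {
  expect_error(compute_chm(matrix(100, 10, 10), gsd = 0.02,
                           segmentation_config(ground_window = 10)),
               class = "config_error")
})

test_that("mask logic: empty on flat CHM, height rule alone at threshold 0", {
  fx <- test_scene()
  sc <- fx$scene
  cube <- sc$reflectance_truth
  chm0 <- matrix(0, nrow(sc$dsm), ncol(sc$dsm))
  expect_false(any(canopy_mask(chm0, cube, fx$grid)))
  chm <- compute_chm(sc$dsm, sc$gsd, segmentation_config())$chm
  cfg0 <- segmentation_config(shadow_threshold = 0)
  expect_identical(canopy_mask(chm, cube, fx$grid, cfg0),
                   chm > cfg0$height_threshold)
  expect_error(canopy_mask(chm[1:5, 1:5], cube, fx$grid),
               class = "shape_error")
})

test_that("default thresholds recover the truth canopy class", {
  fx <- test_scene()
  sc <- fx$scene
  chm <- compute_chm(sc$dsm, sc$gsd, segmentation_config())$chm
  mask <- canopy_mask(chm, sc$reflectance_truth, fx$grid)
  truth <- sc$class_mask == attr(sc$class_mask, "classes")[["canopy"]]
  precision <- sum(mask & truth) / sum(mask)
  recall <- sum(mask & truth) / sum(truth)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("ROI extraction: uniform field, exactness, invariances", {
  fx <- test_scene()
  sc <- fx$scene
  rois <- make_vine_rois(sc)
  chm <- compute_chm(sc$dsm, sc$gsd, segmentation_config())$chm
  mask <- canopy_mask(chm, sc$reflectance_truth, fx$grid)

  # uniform cube -> constant spectra
  uni <- array(0.3, dim = dim(sc$reflectance_truth))
  ds_u <- extract_roi_spectra(uni, mask, rois, fx$grid, sc$gsd,
                              fx$layout$extent_y)
  expect_equal(unique(as.vector(ds_u$spectra)), 0.3)

  # noise-free scene: extracted spectra equal the generated canopy spectra
  ds <- extract_roi_spectra(sc$reflectance_truth, mask, rois, fx$grid,
                            sc$gsd, fx$layout$extent_y)
  expect_equal(nrow(ds$spectra), nrow(rois))
  expect_lt(max(abs(ds$spectra - sc$canopy$spectra[ds$vine_id, ])), 1e-6)

  # permutation invariance in ROI order
  perm <- rev(seq_len(nrow(rois)))
  ds_p <- extract_roi_spectra(sc$reflectance_truth, mask, rois[perm, ],
                              fx$grid, sc$gsd, fx$layout$extent_y)
  expect_equal(ds_p$spectra[perm, ], ds$spectra, ignore_attr = TRUE)

  # bounded by the per-band min/max of masked pixels
  expect_true(all(ds$spectra >= min(sc$reflectance_truth) - 1e-12 &
                    ds$spectra <= max(sc$reflectance_truth) + 1e-12))
})

test_that("single-pixel masks and empty ROIs behave as documented", {
  fx <- test_scene()
  sc <- fx$scene
  rois <- make_vine_rois(sc)[1:2, ]
  mask <- matrix(FALSE, nrow(sc$dsm), ncol(sc$dsm))
  # exactly one canopy pixel inside ROI 1
  classes <- attr(sc$class_mask, "classes")
  can_idx <- which(sc$class_mask == classes[["canopy"]], arr.ind = TRUE)
  ax_x <- (seq_len(ncol(mask)) - 0.5) * sc$gsd
  ax_y <- fx$layout$extent_y - (seq_len(nrow(mask)) - 0.5) * sc$gsd
  inside <- can_idx[ax_x[can_idx[, 2]] >= rois$xmin[1] &
                      ax_x[can_idx[, 2]] <= rois$xmax[1] &
                      ax_y[can_idx[, 1]] >= rois$ymin[1] &
                      ax_y[can_idx[, 1]] <= rois$ymax[1], , drop = FALSE]
  mask[inside[1, 1], inside[1, 2]] <- TRUE
  expect_warning(
    ds <- extract_roi_spectra(sc$reflectance_truth, mask, rois, fx$grid,
                              sc$gsd, fx$layout$extent_y),
    "no masked pixels")
  expect_equal(ds$vine_id, rois$vine_id[1])
  expect_equal(ds$n_pixels, 1L)
  expect_equal(as.vector(ds$spectra),
               sc$reflectance_truth[inside[1, 1], inside[1, 2], ])
  # ROI fully outside the raster errors
  out <- data.frame(vine_id = 99, xmin = 100, xmax = 101, ymin = 100,
                    ymax = 101)
  expect_error(extract_roi_spectra(sc$reflectance_truth,
                                   mask, out, fx$grid, sc$gsd,
                                   fx$layout$extent_y),
               class = "geometry_error")
})
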