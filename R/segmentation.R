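#' Canopy segmentation configuration
#'
#' Parameters of the two-stage canopy filter: a canopy height model built
#' from the digital surface model (moving-window low-percentile ground
#' estimate), thresholded on height, followed by a reflectance threshold in
#' a NIR band that removes shaded leaves and dark soil. Defaults: ground
#' window = 4.8 m (twice the row spacing, so every window sees inter-row
#' ground), 5th percentile, 0.5 m height threshold, shadow test at the band
#' nearest 800 nm with a 0.15 reflectance floor.
#'
#' @param ground_window moving-window size for the ground model (m).
#' @param ground_percentile percentile of the window taken as ground (0-100).
#' @param height_threshold minimum canopy height retained (m).
#' @param shadow_wavelength NIR wavelength of the shadow test (nm).
#' @param shadow_threshold minimum reflectance at `shadow_wavelength`.
#' @param stride evaluation stride (pixels) for the ground percentile
#'   surface, or `"auto"`; `1` evaluates the exact moving window at every
#'   pixel, `"auto"` uses `max(1, floor(window_px / 6))` with bilinear
#'   interpolation between evaluation points.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(ground_window = 4.8, ground_percentile = 5,
                                height_threshold = 0.5,
                                shadow_wavelength = 800,
                                shadow_threshold = 0.15,
                                stride = "auto") {
  if (ground_window <= 0 || height_threshold < 0 || shadow_threshold < 0)
    abort("window and thresholds must be non-negative", "config_error")
  if (ground_percentile < 0 || ground_percentile > 100)
    abort("ground_percentile must lie in [0, 100]", "config_error")
  structure(as.list(environment()), class = "segmentation_config")
}

# Exact moving-window percentile evaluated on a strided grid of pixels, then
# bilinearly interpolated back to full resolution. stride = 1 is the exact
# brute-force moving window.
moving_percentile <- function(m, window_px, prob, stride = 1) {
  ny <- nrow(m); nx <- ncol(m)
  h <- window_px %/% 2
  ri <- unique(c(seq(1, ny, by = stride), ny))
  ci <- unique(c(seq(1, nx, by = stride), nx))
  g <- matrix(NA_real_, length(ri), length(ci))
  for (a in seq_along(ri)) {
    rr <- max(1, ri[a] - h):min(ny, ri[a] + h)
    for (b in seq_along(ci)) {
      cc <- max(1, ci[b] - h):min(nx, ci[b] + h)
      g[a, b] <- stats::quantile(m[rr, cc], prob, names = FALSE, type = 7)
    }
  }
  if (stride == 1) return(g)
  interp_bilinear(g, ri, ci, ny, nx)
}

# Separable linear interpolation of values `g` known at grid (ri, ci) onto
# the full 1..ny x 1..nx lattice.
interp_bilinear <- function(g, ri, ci, ny, nx) {
  rows_full <- matrix(NA_real_, ny, length(ci))
  for (b in seq_along(ci))
    rows_full[, b] <- stats::approx(ri, g[, b], xout = seq_len(ny),
                                    rule = 2)$y
  out <- matrix(NA_real_, ny, nx)
  for (r in seq_len(ny))
    out[r, ] <- stats::approx(ci, rows_full[r, ], xout = seq_len(nx),
                              rule = 2)$y
  out
}

#' Canopy height model from a digital surface model
#'
#' Ground is estimated as a moving-window low-percentile surface of the DSM
#' (so raised canopy strips do not contaminate it as long as each window
#' contains inter-row ground); the CHM is the DSM minus ground, floored at
#' zero.
#'
#' @param dsm elevation matrix (m).
#' @param gsd pixel size (m).
#' @param config a [segmentation_config()].
#' @return list `chm` and `ground` matrices.
#' @export
compute_chm <- function(dsm, gsd, config = segmentation_config()) {
  if (any(!is.finite(dsm))) abort("dsm must be finite", "config_error")
  window_px <- max(3L, as.integer(round(config$ground_window / gsd)))
  if (window_px > max(dim(dsm)) * 2)
    abort("ground window larger than the raster", "config_error")
  stride <- config$stride
  if (identical(stride, "auto")) stride <- max(1L, window_px %/% 6L)
  ground <- moving_percentile(dsm, window_px,
                              config$ground_percentile / 100, stride)
  list(chm = pmax(dsm - ground, 0), ground = ground)
}

#' Canopy mask: height rule plus shadow/soil reflectance filter
#'
#' `mask = (CHM > height_threshold) & (R[shadow band] > shadow_threshold)`.
#' A `shadow_threshold` of 0 reduces the mask to the height rule alone
#' (reflectances are strictly positive).
#'
#' @param chm canopy height matrix from [compute_chm()].
#' @param reflectance_cube `ny x nx x B` reflectance array.
#' @param grid band grid (to resolve `shadow_wavelength`).
#' @param config a [segmentation_config()].
#' @return Logical matrix.
#' @export
canopy_mask <- function(chm, reflectance_cube, grid,
                        config = segmentation_config()) {
  d <- dim(reflectance_cube)
  if (!all(dim(chm) == d[1:2]))
    abort("chm and reflectance cube are not aligned", "shape_error")
  b <- nearest_band(grid, config$shadow_wavelength, context = "shadow filter")
  chm > config$height_threshold &
    reflectance_cube[, , b] > config$shadow_threshold
}

#' Extract per-vine mean spectra from ROI polygons
#'
#' For each square ROI, averages the reflectance spectrum over the masked
#' pixels whose centers fall inside the polygon. Vines with no masked pixel
#' are dropped with a warning; the per-vine pixel count is reported.
#'
#' @param reflectance_cube `ny x nx x B` array.
#' @param mask logical canopy mask (same `ny x nx`).
#' @param rois data.frame `vine_id, xmin, xmax, ymin, ymax` (e.g. from
#'   [make_vine_rois()] or [read_geojson_rois()]).
#' @param grid band grid.
#' @param gsd,extent_y raster geometry (north-up pixel-center frame;
#'   `extent_y` defaults to `ny * gsd`).
#' @return A [spectral_dataset()] with `n_pixels` filled in.
#' @export
extract_roi_spectra <- function(reflectance_cube, mask, rois, grid, gsd,
                                extent_y = nrow(mask) * gsd) {
  d <- dim(reflectance_cube)
  stopifnot(all(dim(mask) == d[1:2]))
  x <- (seq_len(d[2]) - 0.5) * gsd
  y <- extent_y - (seq_len(d[1]) - 0.5) * gsd
  n <- nrow(rois)
  spec <- matrix(NA_real_, n, d[3])
  npix <- integer(n)
  flat <- matrix(reflectance_cube, nrow = d[1] * d[2], ncol = d[3])
  for (i in seq_len(n)) {
    in_x <- which(x >= rois$xmin[i] & x <= rois$xmax[i])
    in_y <- which(y >= rois$ymin[i] & y <= rois$ymax[i])
    if (length(in_x) == 0 || length(in_y) == 0)
      abort(sprintf("ROI for vine %s lies outside the raster",
                    rois$vine_id[i]), "geometry_error")
    sel <- as.matrix(expand.grid(row = in_y, col = in_x))
    keep <- mask[sel]
    npix[i] <- sum(keep)
    if (npix[i] > 0) {
      idx <- (sel[keep, "col"] - 1L) * d[1] + sel[keep, "row"]
      spec[i, ] <- colMeans(flat[idx, , drop = FALSE])
    }
  }
  drop <- npix == 0
  if (any(drop))
    warning(sprintf("%d ROI(s) had no masked pixels and were excluded: %s",
                    sum(drop), paste(rois$vine_id[drop], collapse = ", ")))
  spectral_dataset(vine_id = rois$vine_id[!drop],
                   spectra = spec[!drop, , drop = FALSE], grid = grid,
                   n_pixels = npix[!drop])
}
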