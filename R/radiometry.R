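#' Radiometric calibration configuration
#'
#' Per-band factory gain (radiance per count) and dark current (counts) of
#' the camera, as used by [dn_to_radiance()]. For a synthetic scene,
#' [radiometric_config_from_scene()] derives the config from the generator's
#' sensor truth (gain here is the reciprocal of the DN-formation gain).
#'
#' @param gain per-band gain, radiance units per count (> 0).
#' @param dark per-band dark current, counts (>= 0).
#' @param integration_time_ms integration time (ms, > 0); recorded for
#'   provenance.
#' @param dark_domain `"dn"` subtracts dark before the gain
#'   (`L = gain * (DN - dark)`, the physical sensor order, default);
#'   `"radiance"` subtracts a gain-scaled dark after conversion
#'   (`L = gain * DN - gain * dark`). The two are algebraically identical
#'   here but kept explicit because processing chains state them both ways.
#' @return An object of class `radiometric_config`.
#' @export
radiometric_config <- function(gain, dark, integration_time_ms = 1,
                               dark_domain = c("dn", "radiance")) {
  dark_domain <- match.arg(dark_domain)
  if (any(!is.finite(gain)) || any(gain <= 0))
    abort("gains must be finite and > 0", "invalid_argument")
  if (any(dark < 0)) abort("dark current must be >= 0", "invalid_argument")
  if (integration_time_ms <= 0)
    abort("integration time must be > 0", "invalid_argument")
  structure(list(gain = gain, dark = dark,
                 integration_time_ms = integration_time_ms,
                 dark_domain = dark_domain),
            class = "radiometric_config")
}

#' @rdname radiometric_config
#' @param scene a [render_scene()] result.
#' @export
radiometric_config_from_scene <- function(scene) {
  radiometric_config(gain = 1 / scene$radiometry$gain,
                     dark = scene$radiometry$dark)
}

#' Convert a DN cube to at-sensor radiance
#'
#' `L_b = gain_b * (DN_b - dark_b)` per band. Negative radiances (DN below
#' dark) are preserved and reported via the `negative_fraction` attribute so
#' downstream filters, not the calibration, decide validity.
#'
#' @param dn_cube `ny x nx x B` array of counts.
#' @param config a [radiometric_config()].
#' @return Radiance array of the same shape with attribute
#'   `negative_fraction`.
#' @export
dn_to_radiance <- function(dn_cube, config) {
  stopifnot(inherits(config, "radiometric_config"))
  B <- dim(dn_cube)[3]
  if (is.na(B) || B != length(config$gain))
    abort(sprintf("cube has %s bands but config has %d", B %||% "no",
                  length(config$gain)), "shape_error")
  L <- dn_cube
  for (b in seq_len(B))
    L[, , b] <- config$gain[b] * (dn_cube[, , b] - config$dark[b])
  attr(L, "negative_fraction") <- mean(L < 0)
  L
}

#' Mean panel radiance with a one-pixel inner buffer
#'
#' Averages radiance per band over each panel rectangle eroded by one pixel
#' on every side, avoiding mixed boundary pixels.
#'
#' @param radiance_cube radiance array.
#' @param panel_specs list of `list(rect = c(xmin,xmax,ymin,ymax),
#'   reflectance = r)` as stored on a scene.
#' @param gsd,extent_y raster geometry (pixel-center, north-up frame).
#' @return list `radiance` (panels x bands matrix) and `reflectance`.
#' @export
panel_mean_radiance <- function(radiance_cube, panel_specs, gsd, extent_y) {
  d <- dim(radiance_cube)
  x <- (seq_len(d[2]) - 0.5) * gsd
  y <- extent_y - (seq_len(d[1]) - 0.5) * gsd
  L <- matrix(NA_real_, length(panel_specs), d[3])
  for (k in seq_along(panel_specs)) {
    r <- panel_specs[[k]]$rect
    in_x <- x >= r[["xmin"]] + gsd & x <= r[["xmax"]] - gsd
    in_y <- y >= r[["ymin"]] + gsd & y <= r[["ymax"]] - gsd
    if (!any(in_x) || !any(in_y))
      abort(sprintf("panel %d too small for a 1-pixel inner buffer", k),
            "geometry_error")
    sub <- radiance_cube[in_y, in_x, , drop = FALSE]
    L[k, ] <- apply(sub, 3, mean)
  }
  list(radiance = L,
       reflectance = vapply(panel_specs, `[[`, numeric(1), "reflectance"))
}

#' Fit the empirical line method per band
#'
#' Ordinary least squares of known panel reflectance on observed mean panel
#' radiance, independently for every band:
#' `reflectance = slope_b * L + intercept_b`.
#'
#' @param panel_radiance panels x bands matrix of mean radiances.
#' @param panel_reflectance known reflectance fractions (one per panel).
#' @return An `elm_coefficients` object: data.frame `band`, `slope`,
#'   `intercept`, `rms` (fit residual RMS, reflectance units).
#' @export
fit_elm <- function(panel_radiance, panel_reflectance) {
  panel_radiance <- as.matrix(panel_radiance)
  if (nrow(panel_radiance) < 2)
    abort("at least 2 panels are required", "degenerate_fit")
  if (length(panel_reflectance) != nrow(panel_radiance))
    abort("one reflectance per panel required", "shape_error")
  B <- ncol(panel_radiance)
  slope <- intercept <- rms <- numeric(B)
  for (b in seq_len(B)) {
    L <- panel_radiance[, b]
    if (diff(range(L)) <= 0)
      abort(sprintf("zero radiance spread among panels in band %d", b),
            "degenerate_fit")
    fit <- stats::lm(panel_reflectance ~ L)
    slope[b] <- unname(coef(fit)[2]); intercept[b] <- unname(coef(fit)[1])
    rms[b] <- sqrt(mean(residuals(fit)^2))
  }
  structure(data.frame(band = seq_len(B), slope = slope,
                       intercept = intercept, rms = rms),
            class = c("elm_coefficients", "data.frame"))
}

#' Apply empirical line coefficients to a radiance cube
#'
#' @param radiance_cube radiance array (`ny x nx x B`).
#' @param coeffs a [fit_elm()] result.
#' @param clip_policy `"none"` (default) keeps out-of-range reflectances;
#'   `"unit"` clips to `[0, 1]` and records the clipped fraction in the
#'   `clipped_fraction` attribute.
#' @return Reflectance array of the same shape.
#' @export
apply_elm <- function(radiance_cube, coeffs,
                      clip_policy = c("none", "unit")) {
  clip_policy <- match.arg(clip_policy)
  B <- dim(radiance_cube)[3]
  if (is.na(B) || B != nrow(coeffs))
    abort("band count mismatch between cube and coefficients", "shape_error")
  R <- radiance_cube
  for (b in seq_len(B))
    R[, , b] <- coeffs$slope[b] * radiance_cube[, , b] + coeffs$intercept[b]
  if (clip_policy == "unit") {
    clipped <- mean(R < 0 | R > 1)
    R <- pmin(pmax(R, 0), 1)
    attr(R, "clipped_fraction") <- clipped
  }
  attr(R, "negative_fraction") <- NULL
  R
}

#' Full radiometric chain for a synthetic scene
#'
#' DN -> radiance (factory gains, dark current) -> reflectance (empirical
#' line on the scene's panels). Convenience wrapper used by the pipeline and
#' the round-trip tests.
#'
#' @param scene a [render_scene()] result.
#' @param clip_policy forwarded to [apply_elm()].
#' @return list `radiance`, `reflectance`, `coeffs`, `panels`.
#' @export
calibrate_scene <- function(scene, clip_policy = "none") {
  config <- radiometric_config_from_scene(scene)
  L <- dn_to_radiance(scene$dn_cube, config)
  pan <- panel_mean_radiance(L, scene$panel_specs, scene$gsd,
                             scene$layout$extent_y)
  coeffs <- fit_elm(pan$radiance, pan$reflectance)
  R <- apply_elm(L, coeffs, clip_policy)
  list(radiance = L, reflectance = R, coeffs = coeffs, panels = pan)
}
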