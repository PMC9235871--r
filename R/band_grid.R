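#' Sensor band grid
#'
#' Construct the discrete wavelength axis of a frame hyperspectral camera:
#' `n_bands` equally spaced band centers with the first at `lambda_min` and
#' the last at `lambda_max`, each with a common full width at half maximum.
#' The default corresponds to a 50-band 500--900 nm VNIR instrument with
#' ~8 nm FWHM; every wavelength lookup in the index registry resolves
#' against this axis.
#'
#' @param n_bands number of spectral bands (>= 2).
#' @param lambda_min,lambda_max first and last band center (nm).
#' @param fwhm full width at half maximum of each band (nm, > 0).
#' @return An object of class `band_grid` with elements `centers` (nm) and
#'   `fwhm` (nm).
#' @examples
#' g <- make_band_grid()
#' length(g$centers)     # 50
#' diff(g$centers)[1]    # 400/49 ~ 8.16 nm
#' @export
make_band_grid <- function(n_bands = 50, lambda_min = 500, lambda_max = 900,
                           fwhm = 8) {
  if (!is.numeric(n_bands) || length(n_bands) != 1 || n_bands < 2 ||
      n_bands != round(n_bands))
    abort("n_bands must be an integer >= 2", "invalid_argument")
  if (!is.finite(lambda_min) || !is.finite(lambda_max) ||
      lambda_min >= lambda_max)
    abort("lambda_min must be strictly less than lambda_max",
          "invalid_argument")
  if (!is.finite(fwhm) || fwhm <= 0)
    abort("fwhm must be > 0", "invalid_argument")
  structure(list(centers = seq(lambda_min, lambda_max, length.out = n_bands),
                 fwhm = fwhm),
            class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("band_grid: %d bands, %.1f-%.1f nm, FWHM %.1f nm\n",
              length(x$centers), min(x$centers), max(x$centers), x$fwhm))
  invisible(x)
}

n_bands <- function(grid) length(grid$centers)

#' Resolve a nominal wavelength to the nearest band
#'
#' Index formulas cite nominal wavelengths (e.g. 660 nm) while the sensor has
#' discrete centers; this maps a wavelength to the index of the closest
#' center, erroring if none lies within `tolerance`. Ties resolve to the
#' lower index.
#'
#' @param grid a [make_band_grid()] object.
#' @param wavelength nominal wavelength (nm).
#' @param tolerance maximum allowed |center - wavelength| (nm); defaults to
#'   the grid FWHM.
#' @param context optional label (e.g. an index name) used in the error.
#' @return Integer band index (1-based).
#' @export
nearest_band <- function(grid, wavelength, tolerance = grid$fwhm,
                         context = NULL) {
  stopifnot(inherits(grid, "band_grid"))
  if (!is.finite(tolerance) || tolerance <= 0)
    abort("tolerance must be > 0", "invalid_argument")
  d <- abs(grid$centers - wavelength)
  i <- which.min(d)  # which.min returns the first (lower) index on ties
  if (d[i] > tolerance)
    abort(sprintf(
      "wavelength %.1f nm unresolvable%s: nearest center %.2f nm is %.2f nm away (tolerance %.2f)",
      wavelength, if (is.null(context)) "" else paste0(" for ", context),
      grid$centers[i], d[i], tolerance), "unresolvable_wavelength")
  i
}
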