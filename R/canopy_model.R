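#' Trait-coupled canopy forward model
#'
#' A minimal parametric model of a vine canopy reflectance spectrum with
#' known, invertible trait couplings. The spectrum is a logistic red-edge
#' step from a visible baseline up to a NIR plateau, plus a Gaussian green
#' reflectance bump at 550 nm:
#' \deqn{R(\lambda) = v + (N - v)\,\mathrm{logistic}((\lambda-\lambda_{re})/w)
#'   + g\,e^{-(\lambda-550)^2 / (2\cdot 15^2)}}
#' The NIR plateau `N` increases with total leaf area and with (less
#' negative) pre-dawn water potential; the red-edge center shifts to shorter
#' wavelengths under water stress; the green bump tracks a standardized
#' vigor composite (leaf area, pruning weight, yield). Multiplicative
#' lognormal noise emulates residual canopy/illumination variability.
#'
#' @param vis_baseline visible reflectance floor (fraction, in (0,1)).
#' @param nir_plateau_base NIR plateau at cohort-mean traits (fraction).
#' @param green_bump_amplitude green bump at cohort-mean vigor (fraction).
#' @param red_edge_center red-edge inflection at cohort mean (nm, in
#'   (690, 740)).
#' @param red_edge_width logistic width of the red edge (nm).
#' @param coef_nir_tla NIR plateau change per m2 of total leaf area.
#' @param coef_nir_psi NIR plateau change per MPa of pre-dawn potential.
#' @param coef_re_psi red-edge shift per MPa of pre-dawn potential (nm/MPa).
#' @param coef_green_vigor green-bump change per vigor z-score unit.
#' @param noise_sd sd of the lognormal multiplicative noise (0 disables).
#' @return An object of class `canopy_forward_model`.
#' @export
canopy_forward_model <- function(vis_baseline = 0.05,
                                 nir_plateau_base = 0.45,
                                 green_bump_amplitude = 0.04,
                                 red_edge_center = 715,
                                 red_edge_width = 12,
                                 coef_nir_tla = 0.04,
                                 coef_nir_psi = 0.25,
                                 coef_re_psi = 20,
                                 coef_green_vigor = 0.012,
                                 noise_sd = 0.02) {
  refl <- c(vis_baseline, nir_plateau_base, green_bump_amplitude)
  if (any(!is.finite(refl)) || any(refl <= 0) || any(refl >= 1))
    abort("reflectance parameters must lie in (0,1)", "invalid_argument")
  if (red_edge_center <= 690 || red_edge_center >= 740)
    abort("red_edge_center must lie in (690, 740) nm", "invalid_argument")
  if (noise_sd < 0) abort("noise_sd must be >= 0", "invalid_argument")
  structure(list(vis_baseline = vis_baseline,
                 nir_plateau_base = nir_plateau_base,
                 green_bump_amplitude = green_bump_amplitude,
                 red_edge_center = red_edge_center,
                 red_edge_width = red_edge_width,
                 coef_nir_tla = coef_nir_tla,
                 coef_nir_psi = coef_nir_psi,
                 coef_re_psi = coef_re_psi,
                 coef_green_vigor = coef_green_vigor,
                 noise_sd = noise_sd),
            class = "canopy_forward_model")
}

# Cohort-mean anchors and scales used to center the couplings; taken from
# the default trait spec so a cohort drawn from it has near-zero mean offsets.
.trait_anchor <- list(tla = 1.85, psi_pd = -0.5, pwt = 0.48, yield = 3.37,
                      tla_sd = 0.625, pwt_sd = 0.234, yield_sd = 1.759)

# Per-vine deterministic spectrum parameters given traits.
canopy_params <- function(traits, model) {
  a <- .trait_anchor
  tla <- traits$tla %||% rep(a$tla, nrow(traits))
  psi <- traits$psi_pd %||% rep(a$psi_pd, nrow(traits))
  pwt <- traits$pwt %||% rep(a$pwt, nrow(traits))
  yld <- traits$yield %||% rep(a$yield, nrow(traits))
  vigor_z <- ((tla - a$tla) / a$tla_sd + (pwt - a$pwt) / a$pwt_sd +
                (yld - a$yield) / a$yield_sd) / 3
  list(nir = model$nir_plateau_base +
         model$coef_nir_tla * (tla - a$tla) +
         model$coef_nir_psi * (psi - a$psi_pd),
       re_center = model$red_edge_center + model$coef_re_psi * (psi - a$psi_pd),
       green = model$green_bump_amplitude + model$coef_green_vigor * vigor_z)
}

#' Generate per-vine canopy spectra from a trait table
#'
#' Applies the forward model to every vine in `traits`, yielding the
#' n-by-B matrix of canopy reflectance spectra used throughout the
#' chemometrics stages (the "dataset" of mean spectra). With `noise_sd = 0`
#' the mapping trait -> spectrum is exact and deterministic; otherwise
#' band-wise multiplicative lognormal noise is applied under `seed`.
#'
#' @param traits trait table from [sample_traits()] (values must respect the
#'   bounds of `spec` when supplied).
#' @param grid a [make_band_grid()].
#' @param model a [canopy_forward_model()].
#' @param seed integer seed for the noise draw.
#' @param spec optional [trait_spec()]; when given, trait values outside its
#'   bounds raise a domain error.
#' @return A `spectral_dataset`: list with `vine_id`, `spectra` (n x B
#'   matrix, columns named `R_<wavelength>`), `n_pixels` (NA here) and
#'   `grid`.
#' @export
canopy_reflectance <- function(traits, grid, model = canopy_forward_model(),
                               seed = 1, spec = NULL) {
  stopifnot(inherits(grid, "band_grid"), inherits(model, "canopy_forward_model"))
  if (!is.data.frame(traits) || nrow(traits) == 0)
    abort("traits must be a non-empty data.frame", "invalid_argument")
  if (!is.null(spec)) {
    for (i in seq_len(nrow(spec$traits))) {
      nm <- spec$traits$name[i]
      if (!nm %in% names(traits)) next
      v <- traits[[nm]]
      ok <- is.na(v) | (v >= spec$traits$min[i] - 1e-9 &
                          v <= spec$traits$max[i] + 1e-9)
      if (!all(ok))
        abort(sprintf("trait %s outside spec bounds", nm), "domain_error")
    }
  }
  p <- canopy_params(traits, model)
  lam <- grid$centers
  n <- nrow(traits); B <- length(lam)
  step <- logistic(outer(-p$re_center, lam, `+`) / model$red_edge_width)
  bump <- matrix(exp(-(lam - 550)^2 / (2 * 15^2)), n, B, byrow = TRUE)
  R <- model$vis_baseline + (p$nir - model$vis_baseline) * step +
    p$green * bump
  if (model$noise_sd > 0) {
    noise <- with_seed(seed,
                       matrix(exp(rnorm(n * B, 0, model$noise_sd)), n, B))
    R <- R * noise
  }
  R <- pmin(pmax(R, 1e-4), 1 - 1e-4)
  spectral_dataset(vine_id = traits$vine_id %||% seq_len(n),
                   spectra = R, grid = grid)
}

#' Spectral dataset container
#'
#' @param vine_id vector of vine identifiers (one per row of `spectra`).
#' @param spectra n x B matrix of mean reflectance per band.
#' @param grid the [make_band_grid()] the columns align to.
#' @param n_pixels optional per-vine pixel counts behind each mean spectrum.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(vine_id, spectra, grid,
                             n_pixels = rep(NA_integer_, length(vine_id))) {
  spectra <- as.matrix(spectra)
  stopifnot(length(vine_id) == nrow(spectra),
            ncol(spectra) == length(grid$centers))
  colnames(spectra) <- sprintf("R_%.1f", grid$centers)
  structure(list(vine_id = vine_id, spectra = spectra,
                 n_pixels = n_pixels, grid = grid),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("spectral_dataset: %d vines x %d bands\n",
              nrow(x$spectra), ncol(x$spectra)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$spectra)
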