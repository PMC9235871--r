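# Shared fixtures, built in code at test time.

default_grid <- make_band_grid()

# Vegetation-like reference spectrum used by the golden-value suite:
# logistic red edge at 715 nm plus a green bump at 550 nm.
reference_spectrum <- function(grid = default_grid) {
  lam <- grid$centers
  0.05 + 0.4 * plogis((lam - 715) / 12) + 0.04 * exp(-(lam - 550)^2 / 450)
}

# A spectrum whose resolved values at chosen nominal wavelengths are known
# exactly: every band takes `base`, except the bands nearest the names of
# `at` which take the given values.
spectrum_with <- function(at, base = 0.2, grid = default_grid) {
  s <- rep(base, length(grid$centers))
  for (wl in names(at)) s[nearest_band(grid, as.numeric(wl))] <- at[[wl]]
  s
}

# Small rendered scene, memoized per parameter set within a test file run.
.scene_cache <- new.env(parent = emptyenv())
test_scene <- function(noise_free = TRUE, n_rows = 3, vines_per_row = 5,
                       seed = 2) {
  key <- paste(noise_free, n_rows, vines_per_row, seed, sep = "_")
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  grid <- default_grid
  layout <- scene_layout(n_rows = n_rows, vines_per_row = vines_per_row)
  traits <- sample_traits(default_trait_spec(),
                          n_rows * vines_per_row, seed = seed)
  model <- canopy_forward_model(noise_sd = if (noise_free) 0 else 0.02)
  radio <- sensor_radiometry(grid,
                             noise_sd = if (noise_free) 0 else 1,
                             quantize = !noise_free)
  sc <- render_scene(traits, grid, model, layout, radio, seed = seed)
  .scene_cache[[key]] <- list(scene = sc, traits = traits, grid = grid,
                              layout = layout, model = model)
  .scene_cache[[key]]
}
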