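#!/usr/bin/env Rscript
# Stage 2 -- radiometric calibration and canopy extraction, from files only.
#
# Reads the stage-1 artifacts, converts DN to radiance with the factory
# gains and dark current, fits the empirical line on the five reference
# panels, builds the canopy height model and mask, and extracts the
# per-vine mean spectra from the 0.8 x 0.8 m ROIs.

suppressMessages(library(hypervine))

run <- "results/run"
grid <- make_band_grid()

dn <- read_raster(file.path(run, "dn_cube.tif"))
dsm <- read_raster(file.path(run, "dsm.tif"))$data[, , 1]
radio <- read.csv(file.path(run, "sensor_radiometry.csv"))
panels <- read_geojson_rois(file.path(run, "panels.geojson"))
rois <- read_geojson_rois(file.path(run, "rois.geojson"))
extent_y <- nrow(dsm) * dn$gsd

config <- radiometric_config(gain = 1 / radio$gain, dark = radio$dark)
L <- dn_to_radiance(dn$data, config)
cat(sprintf("radiance: %.2f%% of pixels below dark level\n",
            100 * attr(L, "negative_fraction")))

panel_specs <- lapply(seq_len(nrow(panels)), function(k)
  list(rect = c(xmin = panels$xmin[k], xmax = panels$xmax[k],
                ymin = panels$ymin[k], ymax = panels$ymax[k]),
       reflectance = panels$reflectance[k]))
pan <- panel_mean_radiance(L, panel_specs, dn$gsd, extent_y)
coeffs <- fit_elm(pan$radiance, pan$reflectance)
cat(sprintf("empirical line: max per-band residual RMS %.3g reflectance\n",
            max(coeffs$rms)))
write.csv(data.frame(band = coeffs$band, wavelength = grid$centers,
                     slope = coeffs$slope, intercept = coeffs$intercept,
                     rms = coeffs$rms),
          file.path(run, "elm_coefficients.csv"), row.names = FALSE)
refl <- apply_elm(L, coeffs)
write_raster(refl, file.path(run, "reflectance.tif"), dn$gsd,
             grid$centers, "ELM-calibrated reflectance")

seg <- segmentation_config()
chm <- compute_chm(dsm, dn$gsd, seg)
mask <- canopy_mask(chm$chm, refl, grid, seg)
truth <- read_raster(file.path(run, "class_mask.tif"))$data[, , 1]
truth_canopy <- abs(truth - 3) < 0.5
cat(sprintf("canopy mask: precision %.3f, recall %.3f against truth\n",
            sum(mask & truth_canopy) / sum(mask),
            sum(mask & truth_canopy) / sum(truth_canopy)))
write_raster(chm$chm, file.path(run, "chm.tif"), dn$gsd,
             description = "canopy height model (m)")
write_raster(mask + 0, file.path(run, "canopy_mask.tif"), dn$gsd,
             description = "canopy mask (0/1)")

ds <- extract_roi_spectra(refl, mask, rois, grid, dn$gsd, extent_y)
cat(sprintf("extracted dataset {%d x %d}; %d-%d masked px per ROI\n",
            nrow(ds$spectra), ncol(ds$spectra),
            min(ds$n_pixels), max(ds$n_pixels)))
write_spectral_dataset(ds, file.path(run, "spectra.csv"))
cat("stage 2 artifacts written to", run, "\n")
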