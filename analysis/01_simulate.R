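#!/usr/bin/env Rscript
# Stage 1 -- simulate the study block.
#
# Draws the 60-vine trait cohort calibrated to the study's trait-summary
# table, renders the 6-row x 10-vine scene (2.4 x 1 m spacing, 2 cm GSD,
# 50 bands 500-900 nm, five reference panels) and writes every input the
# later stages need under results/run/.

suppressMessages(library(hypervine))

out <- "results/run"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "hypervine"))
grid <- do.call(make_band_grid, cfg$grid)
layout <- do.call(scene_layout, cfg$layout)
spec <- default_trait_spec()
n_vines <- layout$n_rows * layout$vines_per_row

traits <- sample_traits(spec, n_vines, seed = cfg$seed)
summary_tbl <- trait_calibration_summary(traits, spec)
write.csv(summary_tbl, file.path(out, "trait_summary.csv"),
          row.names = FALSE)
cat(sprintf("cohort of %d vines; worst |CV - target| = %.2f points (%s)\n",
            n_vines,
            max(abs(summary_tbl$realized_cv - summary_tbl$target_cv)),
            summary_tbl$name[which.max(abs(summary_tbl$realized_cv -
                                             summary_tbl$target_cv))]))

# water potentials observed on a 30-vine random subset, as in the field
set.seed(cfg$seed + 1000)
psi_sub <- sort(sample.int(n_vines, cfg$ecophys_subset))
traits_obs <- traits
traits_obs$psi_pd[-psi_sub] <- NA
traits_obs$psi_md[-psi_sub] <- NA
write.csv(traits_obs, file.path(out, "traits.csv"), row.names = FALSE)

scene <- render_scene(traits, grid,
                      layout = layout,
                      radiometry = do.call(sensor_radiometry,
                                           c(list(grid = grid),
                                             cfg$radiometry)),
                      seed = cfg$seed)
cat(sprintf("scene: %d x %d px at %.0f cm GSD\n",
            nrow(scene$dsm), ncol(scene$dsm), 100 * scene$gsd))

write_raster(scene$dn_cube, file.path(out, "dn_cube.tif"), scene$gsd,
             grid$centers, "raw DN hypercube")
write_raster(scene$dsm, file.path(out, "dsm.tif"), scene$gsd,
             description = "digital surface model (m)")
write_raster(scene$class_mask + 0, file.path(out, "class_mask.tif"),
             scene$gsd,
             description = "truth classes 1=soil 2=grass 3=canopy 4=shadow 5=panel")
write_geojson(make_vine_rois(scene, cfg$roi_side),
              file.path(out, "rois.geojson"), "polygon")
panels <- do.call(rbind, lapply(seq_along(scene$panel_specs), function(k) {
  r <- scene$panel_specs[[k]]$rect
  data.frame(panel = k, reflectance = scene$panel_specs[[k]]$reflectance,
             xmin = r[["xmin"]], xmax = r[["xmax"]],
             ymin = r[["ymin"]], ymax = r[["ymax"]])
}))
write_geojson(panels, file.path(out, "panels.geojson"), "polygon")
write.csv(data.frame(band = seq_along(grid$centers),
                     wavelength = grid$centers,
                     gain = scene$radiometry$gain,
                     dark = scene$radiometry$dark),
          file.path(out, "sensor_radiometry.csv"), row.names = FALSE)
cat("stage 1 artifacts written to", out, "\n")
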