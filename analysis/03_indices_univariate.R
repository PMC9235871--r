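#!/usr/bin/env Rscript
# Stage 3 -- narrowband index table and univariate trait regressions.
#
# Computes all registered vegetation indices per pixel and averages them
# within each ROI polygon, then regresses every trait on every index and
# writes the R-squared and significance-class matrices.

suppressMessages(library(hypervine))

run <- "results/run"
grid <- make_band_grid()

refl <- read_raster(file.path(run, "reflectance.tif"))
mask <- read_raster(file.path(run, "canopy_mask.tif"))$data[, , 1] > 0.5
rois <- read_geojson_rois(file.path(run, "rois.geojson"))
traits <- read.csv(file.path(run, "traits.csv"))
extent_y <- nrow(mask) * refl$gsd

vi <- compute_all_indices(refl$data, grid, mask, rois, refl$gsd, extent_y,
                          aggregation = "index-mean")
write.csv(vi, file.path(run, "vegetation_indices.csv"), row.names = FALSE)
cat(sprintf("index table: %d vines x %d indices\n", nrow(vi), ncol(vi) - 1))

uni <- univariate_table(vi, traits)
write.csv(uni, file.path(run, "univariate_long.csv"), row.names = FALSE)
r2 <- univariate_matrix(uni, "r_squared")
write.csv(r2, file.path(run, "univariate_r2.csv"), row.names = FALSE)
write.csv(univariate_matrix(uni, "class"),
          file.path(run, "univariate_class.csv"), row.names = FALSE)

# what the table says: best index per trait
num <- as.matrix(r2[, -1])
rownames(num) <- r2$index
best <- vapply(colnames(num), function(tr) {
  i <- which.max(num[, tr])
  sprintf("%s (R2 = %.2f)", rownames(num)[i], num[i, tr])
}, "")
cat("best univariate index per trait:\n")
for (tr in names(best)) cat(sprintf("  %-8s %s\n", tr, best[[tr]]))
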