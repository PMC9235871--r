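#' Default pipeline configuration
#'
#' A flat, human-editable list (serializable as YAML) driving
#' [run_pipeline()]: band grid, scene layout, forward model, sensor
#' radiometry, segmentation thresholds, aggregation mode, the
#' ecophysiology subset size (water potentials are measured on a random
#' subset of the cohort), cross-validation settings and iPLS widths. All
#' randomness derives from the single integer `seed`.
#'
#' @param ... named overrides of the defaults; nested lists (`layout`,
#'   `model`, `radiometry`, `segmentation`) are replaced wholesale if
#'   supplied.
#' @return Named list, class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    grid = list(n_bands = 50, lambda_min = 500, lambda_max = 900, fwhm = 8),
    layout = list(),        # scene_layout() overrides
    model = list(),         # canopy_forward_model() overrides
    radiometry = list(),    # sensor_radiometry() overrides
    segmentation = list(),  # segmentation_config() overrides
    roi_side = 0.8,
    aggregation = "index-mean",
    ecophys_subset = 30,
    cv_k = 3,
    lv_max = NULL,
    ipls_widths = c(10, 5))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of [pipeline_config()] keys.
#' @return A `pipeline_config` (file md5 recorded for the manifest).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste("config not found:", path),
                                "config_error")
  vals <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, vals)
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

#' Run the full simulate-calibrate-segment-extract-index-model pipeline
#'
#' Executes every stage in order on a synthetic scene and writes all
#' intermediates under `out_dir`: the DN cube and DSM (TIFF + JSON
#' sidecar), panel/vine/ROI GeoJSON, the trait table, empirical-line
#' coefficients, the reflectance cube, canopy height model and mask, the
#' per-vine spectral dataset, the vegetation index table, the univariate
#' R-squared and significance matrices, the PLS/iPLS model report, and a
#' manifest (seeds, configuration, per-stage counts). Re-running with the
#' same config reproduces byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()], or a path to a YAML config.
#' @param out_dir output directory (created if needed).
#' @param write_rasters write the (large) raster intermediates? CSV/JSON
#'   outputs are always written.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_rasters = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("stage %s FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, log_path)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), "pipeline_error")
    })
  }
  seed <- config$seed

  ## simulate ----------------------------------------------------------
  grid <- do.call(make_band_grid, config$grid)
  layout <- do.call(scene_layout, config$layout)
  model <- do.call(canopy_forward_model, config$model)
  radio <- do.call(sensor_radiometry, c(list(grid = grid),
                                        config$radiometry))
  spec <- default_trait_spec()
  n_vines <- layout$n_rows * layout$vines_per_row
  traits <- stage("simulate", sample_traits(spec, n_vines, seed))
  # water potentials observed only on a random ecophysiology subset
  if (!is.null(config$ecophys_subset) &&
      config$ecophys_subset < n_vines) {
    sub <- with_seed(seed + 1000,
                     sort(sample.int(n_vines, config$ecophys_subset)))
    traits_obs <- traits
    traits_obs$psi_pd[-sub] <- NA
    traits_obs$psi_md[-sub] <- NA
  } else traits_obs <- traits
  scene <- stage("simulate", render_scene(traits, grid, model, layout,
                                          radio, seed))
  say("simulate: %d vines, %d bands, %d x %d px, gsd %.3f m",
      n_vines, length(grid$centers), nrow(scene$dsm), ncol(scene$dsm),
      layout$gsd)
  write_csv_stable(traits_obs, file.path(out_dir, "traits.csv"))
  rois <- make_vine_rois(scene, config$roi_side)
  write_geojson(rois, file.path(out_dir, "rois.geojson"), "polygon")
  write_geojson(scene$vine_points, file.path(out_dir, "vines.geojson"),
                "point")
  panels <- do.call(rbind, lapply(seq_along(scene$panel_specs), function(k) {
    r <- scene$panel_specs[[k]]$rect
    data.frame(panel = k,
               reflectance = scene$panel_specs[[k]]$reflectance,
               xmin = r[["xmin"]], xmax = r[["xmax"]],
               ymin = r[["ymin"]], ymax = r[["ymax"]])
  }))
  write_geojson(panels, file.path(out_dir, "panels.geojson"), "polygon")
  if (write_rasters) {
    write_raster(scene$dn_cube, file.path(out_dir, "dn_cube.tif"),
                 layout$gsd, grid$centers, "raw DN hypercube")
    write_raster(scene$dsm, file.path(out_dir, "dsm.tif"), layout$gsd,
                 description = "digital surface model (m)")
    write_raster(scene$class_mask + 0, file.path(out_dir, "class_mask.tif"),
                 layout$gsd, description = "truth classes 1=soil 2=grass 3=canopy 4=shadow 5=panel")
  }

  ## calibrate ---------------------------------------------------------
  cal <- stage("calibrate", calibrate_scene(scene))
  say("calibrate: ELM max panel residual %.3g; negative radiance fraction %.3g",
      max(cal$coeffs$rms), attr(cal$radiance, "negative_fraction"))
  coeffs_df <- data.frame(band = cal$coeffs$band,
                          wavelength = grid$centers,
                          slope = cal$coeffs$slope,
                          intercept = cal$coeffs$intercept,
                          rms = cal$coeffs$rms)
  write_csv_stable(coeffs_df, file.path(out_dir, "elm_coefficients.csv"))
  if (write_rasters)
    write_raster(cal$reflectance, file.path(out_dir, "reflectance.tif"),
                 layout$gsd, grid$centers, "ELM-calibrated reflectance")

  ## segment -----------------------------------------------------------
  segcfg <- do.call(segmentation_config, config$segmentation)
  chm <- stage("segment", compute_chm(scene$dsm, layout$gsd, segcfg))
  mask <- stage("segment",
                canopy_mask(chm$chm, cal$reflectance, grid, segcfg))
  say("segment: %d canopy pixels (%.1f%% of scene)", sum(mask),
      100 * mean(mask))
  if (write_rasters) {
    write_raster(chm$chm, file.path(out_dir, "chm.tif"), layout$gsd,
                 description = "canopy height model (m)")
    write_raster(mask + 0, file.path(out_dir, "canopy_mask.tif"),
                 layout$gsd, description = "canopy mask (0/1)")
  }

  ## extract -----------------------------------------------------------
  ds <- stage("extract",
              extract_roi_spectra(cal$reflectance, mask, rois, grid,
                                  layout$gsd, layout$extent_y))
  say("extract: dataset {%d x %d}, median %d px per ROI",
      nrow(ds$spectra), ncol(ds$spectra),
      as.integer(stats::median(ds$n_pixels)))
  write_spectral_dataset(ds, file.path(out_dir, "spectra.csv"))

  ## indices -----------------------------------------------------------
  vi <- stage("indices",
              if (config$aggregation == "index-mean")
                compute_all_indices(cal$reflectance, grid, mask, rois,
                                    layout$gsd, layout$extent_y,
                                    aggregation = "index-mean")
              else compute_all_indices(ds))
  say("indices: %d indices x %d vines (%s aggregation)",
      ncol(vi) - 1, nrow(vi), config$aggregation)
  write_csv_stable(vi, file.path(out_dir, "vegetation_indices.csv"))

  ## univariate --------------------------------------------------------
  uni <- stage("univariate", univariate_table(vi, traits_obs))
  write_csv_stable(uni, file.path(out_dir, "univariate_long.csv"))
  write_csv_stable(univariate_matrix(uni, "r_squared"),
                   file.path(out_dir, "univariate_r2.csv"))
  write_csv_stable(univariate_matrix(uni, "class"),
                   file.path(out_dir, "univariate_class.csv"))

  ## pls / ipls --------------------------------------------------------
  n_psi <- sum(!is.na(traits_obs$psi_pd))
  say("pls: full dataset {%d x %d}; ecophysiology subset {%d x %d}",
      nrow(ds$spectra), ncol(ds$spectra), n_psi, ncol(ds$spectra))
  report <- stage("pls", build_model_report(ds, traits_obs,
                                            lv_max = config$lv_max,
                                            k = config$cv_k, seed = seed,
                                            widths = config$ipls_widths))
  write_csv_stable(report, file.path(out_dir, "model_report.csv"))

  ## manifest ----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("hypervine")),
    seed = seed,
    config_md5 = attr(config, "md5") %||% NA,
    config = unclass(config),
    counts = list(n_vines = n_vines, n_bands = length(grid$centers),
                  n_indices = ncol(vi) - 1,
                  n_traits = ncol(traits_obs) - 1,
                  n_ecophys = n_psi,
                  scene_px = unname(dim(scene$dsm)),
                  canopy_px = sum(mask),
                  rois_retained = nrow(ds$spectra),
                  report_rows = nrow(report)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, log_path)
  invisible(list(scene = scene, calibration = cal, chm = chm, mask = mask,
                 dataset = ds, vi = vi, univariate = uni, report = report,
                 traits = traits_obs, manifest = manifest))
}
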