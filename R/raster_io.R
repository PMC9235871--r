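# Raster and geometry I/O.
#
# Rasters are stored as multi-page 32-bit float TIFF (one page per band) in
# a local metric, north-up, pixel-center frame, with a JSON sidecar
# (<path>.json) carrying extent, gsd, band wavelengths and the affine
# offset/scale used to map each page into the [0,1] range the TIFF writer
# stores. Geometries travel as GeoJSON in the same local frame.

#' Write / read a multi-band raster
#'
#' @param x matrix (single band) or `ny x nx x B` array.
#' @param path output `.tif` path; a `<path>.json` sidecar is written too.
#' @param gsd ground sampling distance (m/pixel).
#' @param wavelengths optional band-center wavelengths recorded per page.
#' @param description free-text note stored in the sidecar.
#' @return `path`, invisibly; `read_raster()` returns a list with `data`
#'   (always a 3-D array), `gsd`, `wavelengths`, `description`.
#' @export
write_raster <- function(x, path, gsd, wavelengths = NULL,
                         description = "") {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  stopifnot(length(dim(x)) == 3)
  B <- dim(x)[3]
  off <- sc <- numeric(B)
  pages <- vector("list", B)
  for (b in seq_len(B)) {
    v <- x[, , b]
    off[b] <- min(v); sc[b] <- max(v) - min(v)
    pages[[b]] <- if (sc[b] > 0) (v - off[b]) / sc[b] else v * 0
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(ny = dim(x)[1], nx = dim(x)[2], n_bands = B, gsd = gsd,
               offset = off, scale = sc,
               wavelengths = wavelengths, description = description)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  B <- length(pages)
  out <- array(NA_real_, dim = c(meta$ny, meta$nx, B))
  for (b in seq_len(B))
    out[, , b] <- pages[[b]] * meta$scale[b] + meta$offset[b]
  list(data = out, gsd = meta$gsd, wavelengths = meta$wavelengths,
       description = meta$description)
}

# -- GeoJSON ------------------------------------------------------------

rect_coords <- function(r) {
  list(list(c(r[["xmin"]], r[["ymin"]]), c(r[["xmax"]], r[["ymin"]]),
            c(r[["xmax"]], r[["ymax"]]), c(r[["xmin"]], r[["ymax"]]),
            c(r[["xmin"]], r[["ymin"]])))
}

#' Write rectangles or points as a GeoJSON FeatureCollection
#'
#' @param df data.frame; rectangles need `xmin/xmax/ymin/ymax`, points need
#'   `x/y`; all other columns become feature properties.
#' @param path output path.
#' @param geometry `"polygon"` or `"point"`.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(df, path, geometry = c("polygon", "point")) {
  geometry <- match.arg(geometry)
  geo_cols <- if (geometry == "polygon") c("xmin", "xmax", "ymin", "ymax")
    else c("x", "y")
  props <- setdiff(names(df), geo_cols)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    geom <- if (geometry == "polygon")
      list(type = "Polygon",
           coordinates = rect_coords(as.list(df[i, geo_cols])))
    else list(type = "Point", coordinates = c(df$x[i], df$y[i]))
    list(type = "Feature", geometry = geom,
         properties = as.list(df[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read rectangle ROI polygons from GeoJSON
#'
#' Reads a FeatureCollection of polygons and returns each feature's bounding
#' box with its properties (axis-aligned square ROIs round-trip exactly).
#'
#' @param path GeoJSON path.
#' @return data.frame with properties + `xmin/xmax/ymin/ymax`.
#' @export
read_geojson_rois <- function(path) {
  g <- jsonlite::read_json(path)
  rows <- lapply(g$features, function(f) {
    cc <- f$geometry$coordinates[[1]]
    xs <- vapply(cc, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(cc, function(p) as.numeric(p[[2]]), numeric(1))
    c(f$properties,
      list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

# -- spectral dataset CSV ------------------------------------------------

#' Write / read a spectral dataset as CSV
#'
#' Columns: `vine_id`, `n_pixels`, then one `R_<wavelength>` column per band
#' (wavelengths rounded to 0.1 nm in the header).
#'
#' @param ds a [spectral_dataset()].
#' @param path CSV path.
#' @param grid band grid used to rebuild the dataset on read.
#' @return `path` / a `spectral_dataset`.
#' @export
write_spectral_dataset <- function(ds, path) {
  df <- data.frame(vine_id = ds$vine_id, n_pixels = ds$n_pixels)
  df <- cbind(df, as.data.frame(ds$spectra))
  write_csv_stable(df, path)
}

#' @rdname write_spectral_dataset
#' @export
read_spectral_dataset <- function(path, grid) {
  df <- utils::read.csv(path, check.names = FALSE)
  spectral_dataset(vine_id = df$vine_id,
                   spectra = as.matrix(df[, -(1:2), drop = FALSE]),
                   grid = grid, n_pixels = df$n_pixels)
}
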