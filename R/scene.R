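#' Vineyard scene layout
#'
#' Geometry of the synthetic vineyard: NS-oriented rows on a regular
#' between-row / within-row spacing (default 2.4 x 1 m, the study trellis),
#' canopy strips of a given width and height, a shaded strip on the east
#' side of each row, grass strips mid inter-row, five calibration panels in
#' the southern margin, and the ground sampling distance.
#'
#' @param n_rows,vines_per_row vineyard dimensions (default 6 x 10 = 60
#'   vines).
#' @param row_spacing,vine_spacing between- and within-row spacing (m).
#' @param row_width canopy strip width (m).
#' @param canopy_height canopy top above ground (m).
#' @param shade_width width of the shadow strip east of each row (m).
#' @param shade_factor multiplicative shading of the canopy spectrum.
#' @param grass_width width of the grass strip centered between rows (m).
#' @param margin unplanted margin around the block (m); must fit the panels.
#' @param panel_size reference panel side (m).
#' @param panel_reflectances known panel reflectances (fractions).
#' @param gsd ground sampling distance (m/pixel).
#' @param ground_elevation flat ground elevation (m).
#' @return An object of class `scene_layout`.
#' @export
scene_layout <- function(n_rows = 6, vines_per_row = 10,
                         row_spacing = 2.4, vine_spacing = 1,
                         row_width = 0.6, canopy_height = 1.8,
                         shade_width = 0.4, shade_factor = 0.25,
                         grass_width = 0.8, margin = 2,
                         panel_size = 0.5,
                         panel_reflectances = c(0.02, 0.09, 0.25, 0.50, 0.88),
                         gsd = 0.02, ground_elevation = 100) {
  l <- as.list(environment())
  l$extent_x <- 2 * margin + (n_rows - 1) * row_spacing + row_width
  l$extent_y <- 2 * margin + (vines_per_row - 1) * vine_spacing +
    vine_spacing
  structure(l, class = "scene_layout")
}

# Pixel-center coordinate vectors for a layout (north-up: row 1 = north).
scene_axes <- function(layout) {
  nx <- ceiling(layout$extent_x / layout$gsd)
  ny <- ceiling(layout$extent_y / layout$gsd)
  list(nx = nx, ny = ny,
       x = (seq_len(nx) - 0.5) * layout$gsd,
       y = layout$extent_y - (seq_len(ny) - 0.5) * layout$gsd)
}

# Vine positions: row i at x = margin + row_width/2 + (i-1)*row_spacing,
# vine j at y = margin + vine_spacing/2 + (j-1)*vine_spacing.
vine_positions <- function(layout) {
  xs <- layout$margin + layout$row_width / 2 +
    (seq_len(layout$n_rows) - 1) * layout$row_spacing
  ys <- layout$margin + layout$vine_spacing / 2 +
    (seq_len(layout$vines_per_row) - 1) * layout$vine_spacing
  data.frame(vine_id = seq_len(layout$n_rows * layout$vines_per_row),
             row = rep(seq_len(layout$n_rows), each = layout$vines_per_row),
             x = rep(xs, each = layout$vines_per_row),
             y = rep(ys, times = layout$n_rows))
}

# Fixed background endmember spectra (fractions on the band grid).
soil_spectrum <- function(lam) 0.12 + 0.18 * (lam - 500) / 400
grass_spectrum <- function(lam)
  0.06 + 0.30 * logistic((lam - 710) / 15) + 0.05 * exp(-(lam - 552)^2 / 450)

#' Smooth solar-like at-sensor illumination curve
#'
#' Relative spectral irradiance used to turn surface reflectance into
#' at-sensor radiance (`L = E * R`); a gentle smooth curve peaking in the
#' green, in arbitrary radiance units. The empirical line method must
#' recover its inverse per band.
#'
#' @param lam wavelengths (nm).
#' @return Positive vector the length of `lam`.
#' @export
illumination_curve <- function(lam)
  0.85 + 0.35 * exp(-((lam - 560) / 190)^2)

#' Sensor radiometric truth used by the generator
#'
#' Per-band DN gain (counts per radiance unit), dark current (counts) and
#' additive DN noise. The rendered cube is
#' `DN = round(gain * L + dark + noise)` (rounding off when
#' `quantize = FALSE`, the noise-free configuration used by exactness
#' checks).
#'
#' @param grid band grid.
#' @param gain_base,gain_slope per-band gain = `gain_base + gain_slope *
#'   (lambda - 500)`.
#' @param dark dark current (counts, recycled per band).
#' @param noise_sd additive DN noise sd (counts).
#' @param quantize round DN to integers?
#' @return list of per-band vectors + flags, class `sensor_radiometry`.
#' @export
sensor_radiometry <- function(grid, gain_base = 600, gain_slope = 0.25,
                              dark = 40, noise_sd = 1, quantize = TRUE) {
  lam <- grid$centers
  gain <- gain_base + gain_slope * (lam - 500)
  structure(list(gain = gain, dark = rep_len(dark, length(lam)),
                 noise_sd = noise_sd, quantize = quantize,
                 illumination = illumination_curve(lam)),
            class = "sensor_radiometry")
}

#' Render a synthetic vineyard scene
#'
#' Rasterizes the layout into a class-truth mask (soil / grass / canopy /
#' shadow / panel), a per-pixel vine assignment, a digital surface model
#' (flat ground + raised canopy strips), a ground-truth reflectance cube and
#' the derived DN cube through the sensor radiometry. Canopy pixels carry the
#' exact per-vine spectrum from [canopy_reflectance()]; shadow pixels the
#' nearest vine's spectrum scaled by `shade_factor`; panels their known flat
#' reflectance.
#'
#' @param traits trait table with one row per vine
#'   (`n_rows * vines_per_row`).
#' @param grid band grid.
#' @param model canopy forward model.
#' @param layout a [scene_layout()].
#' @param radiometry a [sensor_radiometry()].
#' @param seed integer seed (canopy noise and DN noise).
#' @return An object of class `scene_raster`; see Details.
#' @details The returned list holds `dn_cube` and `reflectance_truth`
#'   (`ny x nx x B` arrays), `dsm`, `ground_elevation`, `class_mask`
#'   (integer, levels in `attr(.,"classes")`), `vine_map`, `panel_specs`
#'   (list of rectangles + reflectance), `vine_points`, `gsd`, `layout`,
#'   `grid`, `radiometry` and the per-vine `canopy` spectra used.
#' @export
render_scene <- function(traits, grid, model = canopy_forward_model(),
                         layout = scene_layout(),
                         radiometry = sensor_radiometry(grid), seed = 1) {
  n_vines <- layout$n_rows * layout$vines_per_row
  if (nrow(traits) != n_vines)
    abort(sprintf("traits has %d rows but layout defines %d vines",
                  nrow(traits), n_vines), "layout_error")
  need_x <- 2 * layout$margin +
    (layout$n_rows - 1) * layout$row_spacing + layout$row_width
  if (layout$extent_x < need_x - 1e-9 ||
      layout$margin < layout$panel_size + 0.2)
    abort("layout cannot fit all vines and panels", "layout_error")
  panels_w <- length(layout$panel_reflectances) * (layout$panel_size + 0.5)
  if (panels_w > layout$extent_x)
    abort("layout cannot fit the reference panels", "layout_error")

  ax <- scene_axes(layout)
  lam <- grid$centers; B <- length(lam)
  vp <- vine_positions(layout)

  ## class mask ---------------------------------------------------------
  classes <- c(soil = 1L, grass = 2L, canopy = 3L, shadow = 4L, panel = 5L)
  cls <- matrix(classes[["soil"]], ax$ny, ax$nx)
  vine_map <- matrix(0L, ax$ny, ax$nx)

  row_x <- unique(vp$x)
  y0 <- layout$margin; y1 <- layout$margin +
    (layout$vines_per_row - 1) * layout$vine_spacing + layout$vine_spacing
  in_y <- ax$y >= y0 & ax$y <= y1
  # grass strips centered between rows
  if (layout$n_rows > 1) for (i in seq_len(layout$n_rows - 1)) {
    xm <- (row_x[i] + row_x[i + 1]) / 2
    in_x <- ax$x >= xm - layout$grass_width / 2 &
      ax$x <= xm + layout$grass_width / 2
    cls[in_y, in_x] <- classes[["grass"]]
  }
  # canopy strips and east-side shadow strips
  for (i in seq_along(row_x)) {
    in_x_can <- ax$x >= row_x[i] - layout$row_width / 2 &
      ax$x <= row_x[i] + layout$row_width / 2
    in_x_sh <- ax$x > row_x[i] + layout$row_width / 2 &
      ax$x <= row_x[i] + layout$row_width / 2 + layout$shade_width
    cls[in_y, in_x_sh] <- classes[["shadow"]]
    cls[in_y, in_x_can] <- classes[["canopy"]]
    # nearest vine along the row
    vid <- vp$vine_id[vp$row == i]
    vy <- vp$y[vp$row == i]
    j <- pmin(pmax(findInterval(ax$y[in_y], sort(vy) -
                                  layout$vine_spacing / 2) , 1L),
              length(vy))
    # vy ascends south->north while rows of the matrix run north->south;
    # findInterval needs the ascending order, then map back
    ord <- order(vy)
    near <- vid[ord][j]
    for (k in c("canopy", "shadow")) {
      xx <- if (k == "canopy") in_x_can else in_x_sh
      vm <- vine_map[in_y, xx, drop = FALSE]
      vm[] <- near
      vine_map[in_y, xx] <- vm
    }
  }
  # panels in the southern margin
  panel_specs <- vector("list", length(layout$panel_reflectances))
  px0 <- 0.3
  for (k in seq_along(layout$panel_reflectances)) {
    x0 <- px0 + (k - 1) * (layout$panel_size + 0.5)
    rect <- c(xmin = x0, xmax = x0 + layout$panel_size,
              ymin = 0.3, ymax = 0.3 + layout$panel_size)
    in_x <- ax$x >= rect["xmin"] & ax$x <= rect["xmax"]
    in_yp <- ax$y >= rect["ymin"] & ax$y <= rect["ymax"]
    cls[in_yp, in_x] <- classes[["panel"]]
    panel_specs[[k]] <- list(rect = rect,
                             reflectance = layout$panel_reflectances[k])
  }

  ## surface model ------------------------------------------------------
  dsm <- matrix(layout$ground_elevation, ax$ny, ax$nx)
  dsm[cls == classes[["canopy"]]] <-
    layout$ground_elevation + layout$canopy_height

  ## reflectance cube via one lookup table ------------------------------
  canopy <- canopy_reflectance(traits, grid, model, seed = seed)
  # lookup rows: 1 soil, 2 grass, 3..(2+n) canopy vine v, then shadow rows
  lut <- rbind(soil_spectrum(lam), grass_spectrum(lam),
               canopy$spectra, canopy$spectra * layout$shade_factor,
               matrix(rep(layout$panel_reflectances, each = B),
                      ncol = B, byrow = TRUE))
  key <- matrix(1L, ax$ny, ax$nx)
  key[cls == classes[["grass"]]] <- 2L
  can <- cls == classes[["canopy"]]
  key[can] <- 2L + vine_map[can]
  sha <- cls == classes[["shadow"]]
  key[sha] <- 2L + n_vines + vine_map[sha]
  for (k in seq_along(panel_specs)) {
    in_x <- ax$x >= panel_specs[[k]]$rect["xmin"] &
      ax$x <= panel_specs[[k]]$rect["xmax"]
    in_yp <- ax$y >= panel_specs[[k]]$rect["ymin"] &
      ax$y <= panel_specs[[k]]$rect["ymax"]
    key[in_yp, in_x] <- 2L + 2L * n_vines + k
  }
  refl <- array(lut[key, ], dim = c(ax$ny, ax$nx, B))

  ## DN formation -------------------------------------------------------
  dn <- refl
  for (b in seq_len(B))
    dn[, , b] <- radiometry$gain[b] *
      (radiometry$illumination[b] * refl[, , b]) + radiometry$dark[b]
  if (radiometry$noise_sd > 0)
    dn <- dn + with_seed(seed + 1,
                         array(rnorm(length(dn), 0, radiometry$noise_sd),
                               dim = dim(dn)))
  if (radiometry$quantize) dn <- round(dn)

  structure(list(dn_cube = dn, reflectance_truth = refl, dsm = dsm,
                 ground_elevation = layout$ground_elevation,
                 class_mask = structure(cls, classes = classes),
                 vine_map = vine_map, panel_specs = panel_specs,
                 vine_points = vp[, c("vine_id", "x", "y")],
                 gsd = layout$gsd, layout = layout, grid = grid,
                 radiometry = radiometry, canopy = canopy),
            class = "scene_raster")
}

#' @export
print.scene_raster <- function(x, ...) {
  d <- dim(x$dn_cube)
  cat(sprintf("scene_raster: %d x %d px, %d bands, gsd %.3f m, %d vines\n",
              d[1], d[2], d[3], x$gsd, nrow(x$vine_points)))
  invisible(x)
}

#' Square regions of interest centered on each vine
#'
#' @param scene a [render_scene()] result (or anything with `vine_points`).
#' @param side ROI side length (m); the study protocol uses 0.8 m squares.
#' @return data.frame `vine_id, xmin, xmax, ymin, ymax`.
#' @export
make_vine_rois <- function(scene, side = 0.8) {
  vp <- scene$vine_points
  data.frame(vine_id = vp$vine_id,
             xmin = vp$x - side / 2, xmax = vp$x + side / 2,
             ymin = vp$y - side / 2, ymax = vp$y + side / 2)
}
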