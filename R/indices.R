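#' First-derivative spectrum
#'
#' Central differences with respect to wavelength on the interior bands and
#' one-sided differences at the two endpoints; units reflectance per nm.
#' Constant spectra map to exactly zero everywhere.
#'
#' @param x spectrum vector (length B) or n x B matrix.
#' @param grid band grid.
#' @return Same shape as `x`.
#' @export
first_derivative <- function(x, grid) {
  lam <- grid$centers
  B <- length(lam)
  if (B < 3) abort("need at least 3 bands for derivatives", "size_error")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != B) abort("spectrum length must match grid", "size_error")
  D <- X
  D[, 2:(B - 1)] <- (X[, 3:B] - X[, 1:(B - 2)]) /
    rep(lam[3:B] - lam[1:(B - 2)], each = nrow(X))
  D[, 1] <- (X[, 2] - X[, 1]) / (lam[2] - lam[1])
  D[, B] <- (X[, B] - X[, B - 1]) / (lam[B] - lam[B - 1])
  if (vec) drop(D) else D
}

# The registry: one entry per distinct index printed in the source formula
# table. Each evaluator receives
#   R(wl)        reflectance column at the band nearest wl
#   DW(a, b, op) max or sum of the first-derivative spectrum over all bands
#                whose centers lie in [a, b] nm (or just the two named
#                bands when dhvi_mode = "pair")
# Formula strings are kept verbatim for the audit dump; several differ from
# the literature's canonical forms (band pairs, signs, the red-edge position
# structure) and are implemented exactly as printed.
vi_entries <- function() {
  nd <- function(a, b) function(R, DW) safe_div(R(a) - R(b), R(a) + R(b))
  e <- list()
  add <- function(name, full, group, formula, fun, deriv = FALSE,
                  printed_twice = FALSE)
    e[[length(e) + 1]] <<- list(name = name, full_name = full, group = group,
                                formula = formula, fun = fun,
                                uses_derivative = deriv,
                                printed_twice = printed_twice)
  add("NDVI1", "Normalized difference vegetation index", "NIR, VIS",
      "(R850-R660)/(R850+R660)", nd(850, 660))
  add("NDVI2", "Normalized difference vegetation index", "NIR, VIS",
      "(R835-R660)/(R835+R660)", nd(835, 660))
  add("NDVI3", "Normalized difference vegetation index", "NIR, VIS",
      "(R850-R660)/(R850+R660)", nd(850, 660))
  add("GNDVI1", "Green NDVI", "NIR, VIS",
      "(R850-R540)/(R850+R540)", nd(850, 540))
  add("GNDVI2", "Green NDVI", "NIR, VIS",
      "(R780-R550)/(R780+R550)", nd(780, 550))
  add("SAVI", "Soil-adjusted vegetation index", "NIR, VIS",
      "(1+0.5)*(R802-R660)/(R802+R660+0.5)",
      function(R, DW) 1.5 * safe_div(R(802) - R(660), R(802) + R(660) + 0.5))
  add("RENDVI", "Red edge normalized difference vegetation index", "NIR, RE",
      "(R850-R680)/(R850+R680)", nd(850, 680))
  add("NDRE", "Normalized difference nir/red edge index", "NIR, RE",
      "(R770-R750)/(R770+R750)", nd(770, 750))
  add("NRER", "Nir-re-red normalized difference vegetation index",
      "NIR, RE, VIS", "(R850-R695)/(R695+R660)",
      function(R, DW) safe_div(R(850) - R(695), R(695) + R(660)),
      printed_twice = TRUE)
  add("TCARI", "Transformed chlorophyll absorption ratio", "NIR, RE, VIS",
      "3*((R695-R663)-0.2*(R695-R540)*(R695/R663))",
      function(R, DW) 3 * ((R(695) - R(663)) -
                             0.2 * (R(695) - R(540)) *
                             safe_div(R(695), R(663))))
  add("MTVI1", "Modified triangular vegetation index", "NIR, RE, VIS",
      "1.2*(1.2*(R800-R540)-2.5*(R660-R540))",
      function(R, DW) 1.2 * (1.2 * (R(800) - R(540)) -
                               2.5 * (R(660) - R(540))))
  add("MTVI2", "Modified triangular vegetation index", "NIR, RE, VIS",
      "1.2*(1.2*(R800-R550)-2.5*(R670-R550))",
      function(R, DW) 1.2 * (1.2 * (R(800) - R(550)) -
                               2.5 * (R(670) - R(550))))
  add("EVI", "Enhanced vegetation index", "NIR, RE, VIS",
      "2.5*(R850-R660)/(R850+6*R660-7.5*R505)+1",
      function(R, DW) 2.5 * safe_div(R(850) - R(660),
                                     R(850) + 6 * R(660) - 7.5 * R(505)) + 1)
  add("LCI", "Leaf chlorophyll index", "NIR, RE, VIS",
      "(R850-R710)/(R850+R680)",
      function(R, DW) safe_div(R(850) - R(710), R(850) + R(680)))
  add("MTCIvar", "Meris terrestrial chlorophyll index", "NIR, RE",
      "(R850-R680)/(R680+R660)",
      function(R, DW) safe_div(R(850) - R(680), R(680) + R(660)))
  add("NRI", "Nitrogen reflectance index", "NIR, RE",
      "(R555-R550)/(R555+R550)", nd(555, 550))
  add("PRI", "Photochemical reflectance index", "NIR, RE",
      "(R570-R530)/(R570+R530)", nd(570, 530))
  add("SPVI", "Spectral polygon vegetation index", "NIR, RE, VIS",
      "0.4*(3.7*(R800-R670)-1.2*(R530-R670))",
      function(R, DW) 0.4 * (3.7 * (R(800) - R(670)) -
                               1.2 * (R(530) - R(670))))
  add("SR710", "Simple ratio 710", "RE", "R750/R710",
      function(R, DW) safe_div(R(750), R(710)))
  add("SR680", "Simple ratio 680", "RE", "R800/R680",
      function(R, DW) safe_div(R(800), R(680)))
  add("RVI", "Ratio vegetation index", "NIR, VIS", "R810/R660",
      function(R, DW) safe_div(R(810), R(660)))
  add("VOG1", "Vogelmann index", "RE", "R745/R720",
      function(R, DW) safe_div(R(745), R(720)))
  add("GM", "Gitelson and Merzlyak index", "RE, VIS", "R750/R550",
      function(R, DW) safe_div(R(750), R(550)))
  add("MNDm", "Modified normalized difference", "NIR, RE, VIS",
      "(R750-R705)/(R750+R705-2*R508)",
      function(R, DW) safe_div(R(750) - R(705),
                               R(750) + R(705) - 2 * R(508)))
  add("NDRE2", "Normalized difference nir/red edge index", "NIR, RE, VIS",
      "(R795-R720)/(R795+R720)", nd(795, 720))
  add("MCARI2", "Modified chlorophyll absorption in reflectance",
      "NIR, RE, VIS", "(R750-R705)-0.2*(R750-R550)*(R750/R705)",
      function(R, DW) (R(750) - R(705)) -
        0.2 * (R(750) - R(550)) * safe_div(R(750), R(705)))
  add("TVI", "Triangular vegetation index", "NIR, RE, VIS",
      "0.5*(120*(R750-R550)-200*(R670-R550))",
      function(R, DW) 0.5 * (120 * (R(750) - R(550)) -
                               200 * (R(670) - R(550))))
  add("EVI2", "Enhanced vegetation index (rep)", "NIR, RE, VIS",
      "2.5*(R800-R670)/(R800+6*R670-7.5*R508)+1",
      function(R, DW) 2.5 * safe_div(R(800) - R(670),
                                     R(800) + 6 * R(670) - 7.5 * R(508)) + 1)
  add("REP", "Red Edge position index", "NIR, RE, VIS",
      "700+(45*R670+R778)/2-(R850)/(R735-R695)",
      function(R, DW) 700 + (45 * R(670) + R(778)) / 2 -
        safe_div(R(850), R(735) - R(695)))
  dhvi <- function(name, full, group, a, b, op) add(
    name, full, group,
    sprintf("%s[D%d, D%d]", if (op == "max") "Max " else "Sum ", a, b),
    function(R, DW) DW(a, b, op), deriv = TRUE)
  dhvi("maxR", "1st Derivative Max RED index", "dHVI-VIS", 660, 680, "max")
  dhvi("sumR", "1st Derivative Sum RED index", "dHVI-VIS", 660, 680, "sum")
  dhvi("maxRE", "1st Derivative Max RE index", "dHVI-RE", 690, 700, "max")
  dhvi("sumRE", "1st Derivative Sum RE index", "dHVI-RE", 690, 700, "sum")
  dhvi("maxLARE", "1st Derivative Max LARE index", "dHVI-RE", 690, 710, "max")
  dhvi("sumLARE", "1st Derivative Sum LARE index", "dHVI-RE", 690, 710, "sum")
  dhvi("maxNIR", "1st Derivative Max NIR index", "dHVI-NIR", 790, 840, "max")
  dhvi("sumNIR", "1st Derivative Sum NIR index", "dHVI-NIR", 790, 840, "sum")
  e
}

#' Narrowband vegetation index registry
#'
#' One row per distinct index (the duplicated NRER row of the source table
#' is a single named entry, flagged by `printed_twice`). Formulas are
#' implemented exactly as printed, including the non-canonical variants
#' (NDVI1 and NDVI3 are identical; the red-edge position index keeps the
#' printed arithmetic structure).
#'
#' @return data.frame `name`, `full_name`, `group`, `formula`,
#'   `uses_derivative`, `printed_twice`.
#' @export
vi_registry <- function() {
  e <- vi_entries()
  data.frame(name = vapply(e, `[[`, "", "name"),
             full_name = vapply(e, `[[`, "", "full_name"),
             group = vapply(e, `[[`, "", "group"),
             formula = vapply(e, `[[`, "", "formula"),
             uses_derivative = vapply(e, `[[`, TRUE, "uses_derivative"),
             printed_twice = vapply(e, `[[`, TRUE, "printed_twice"),
             stringsAsFactors = FALSE)
}

# Evaluate all indices over an n x B spectra matrix. Returns n x K matrix.
compute_indices_matrix <- function(X, grid, dhvi_mode = c("window", "pair"),
                                   warn_na = TRUE, entries = vi_entries()) {
  dhvi_mode <- match.arg(dhvi_mode)
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(grid$centers))
    abort("spectra column count must match the band grid", "shape_error")
  need_d <- any(vapply(entries, `[[`, TRUE, "uses_derivative"))
  D <- if (need_d) first_derivative(X, grid) else NULL
  lam <- grid$centers
  out <- matrix(NA_real_, nrow(X), length(entries),
                dimnames = list(NULL, vapply(entries, `[[`, "", "name")))
  for (k in seq_along(entries)) {
    ent <- entries[[k]]
    Rf <- function(wl) X[, nearest_band(grid, wl, context = ent$name)]
    DW <- function(a, b, op) {
      cols <- if (dhvi_mode == "window") which(lam >= a & lam <= b)
        else c(nearest_band(grid, a, context = ent$name),
               nearest_band(grid, b, context = ent$name))
      if (length(cols) == 0)
        abort(sprintf("no bands in [%g, %g] nm for %s", a, b, ent$name),
              "unresolvable_wavelength")
      sub <- D[, cols, drop = FALSE]
      if (op == "max") apply(sub, 1, max) else rowSums(sub)
    }
    v <- ent$fun(Rf, DW)
    if (warn_na && anyNA(v))
      warning(sprintf("index %s undefined (zero denominator) for %d spectrum/spectra",
                      ent$name, sum(is.na(v))))
    out[, k] <- v
  }
  out
}

#' Compute one index on one spectrum
#'
#' @param name registered index name.
#' @param spectrum reflectance vector on `grid`.
#' @param grid band grid.
#' @param dhvi_mode `"window"` (derivative max/sum over all bands in the
#'   printed nm interval, default) or `"pair"` (the two named bands only).
#' @return Scalar value (`NA` with a warning if undefined).
#' @export
compute_index <- function(name, spectrum, grid, dhvi_mode = "window") {
  entries <- vi_entries()
  hit <- which(vapply(entries, `[[`, "", "name") == name)
  if (length(hit) == 0)
    abort(sprintf("unknown index '%s'", name), "invalid_argument")
  compute_indices_matrix(spectrum, grid, dhvi_mode,
                         entries = entries[hit])[1, name]
}

#' Per-vine vegetation index table
#'
#' Two aggregation modes mirror the two orders of averaging: `"index-mean"`
#' computes every index per pixel and averages the defined values within
#' each ROI (the study's order for the index table); `"spectrum-mean"`
#' computes indices on the ROI-mean spectrum (the order behind the
#' chemometrics dataset). For a bare [spectral_dataset()] only
#' `"spectrum-mean"` is possible.
#'
#' @param x a `spectral_dataset`, or a reflectance cube (`ny x nx x B`).
#' @param grid band grid (taken from the dataset if absent).
#' @param mask,rois,gsd,extent_y required when `x` is a cube: canopy mask,
#'   ROI rectangles, geometry.
#' @param aggregation `"index-mean"` or `"spectrum-mean"`.
#' @param dhvi_mode see [compute_index()].
#' @return data.frame `vine_id` + one column per registered index.
#' @export
compute_all_indices <- function(x, grid = NULL, mask = NULL, rois = NULL,
                                gsd = NULL, extent_y = NULL,
                                aggregation = c("index-mean",
                                                "spectrum-mean"),
                                dhvi_mode = "window") {
  aggregation <- match.arg(aggregation)
  if (inherits(x, "spectral_dataset")) {
    vi <- compute_indices_matrix(x$spectra, grid %||% x$grid, dhvi_mode)
    return(data.frame(vine_id = x$vine_id, vi, check.names = FALSE))
  }
  stopifnot(!is.null(mask), !is.null(rois), !is.null(gsd), !is.null(grid))
  d <- dim(x)
  extent_y <- extent_y %||% (d[1] * gsd)
  if (aggregation == "spectrum-mean") {
    ds <- extract_roi_spectra(x, mask, rois, grid, gsd, extent_y)
    return(compute_all_indices(ds, dhvi_mode = dhvi_mode))
  }
  px <- (seq_len(d[2]) - 0.5) * gsd
  py <- extent_y - (seq_len(d[1]) - 0.5) * gsd
  flat <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  reg_names <- vi_registry()$name
  out <- matrix(NA_real_, nrow(rois), length(reg_names),
                dimnames = list(NULL, reg_names))
  all_na <- character(0)
  for (i in seq_len(nrow(rois))) {
    in_x <- which(px >= rois$xmin[i] & px <= rois$xmax[i])
    in_y <- which(py >= rois$ymin[i] & py <= rois$ymax[i])
    sel <- as.matrix(expand.grid(row = in_y, col = in_x))
    keep <- mask[sel]
    if (!any(keep)) next
    idx <- (sel[keep, "col"] - 1L) * d[1] + sel[keep, "row"]
    vi_px <- compute_indices_matrix(flat[idx, , drop = FALSE], grid,
                                    dhvi_mode, warn_na = FALSE)
    m <- colMeans(vi_px, na.rm = TRUE)
    nan <- colSums(!is.na(vi_px)) == 0
    m[nan] <- NA_real_
    if (any(nan)) all_na <- union(all_na, reg_names[nan])
    out[i, ] <- m
  }
  if (length(all_na) > 0)
    warning(sprintf("indices with all-NA pixels in some ROI: %s",
                    paste(all_na, collapse = ", ")))
  data.frame(vine_id = rois$vine_id, out, check.names = FALSE)
}
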