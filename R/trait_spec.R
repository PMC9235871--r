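#' Vine trait specification
#'
#' A `trait_spec` declares, per trait, the target mean, range and coefficient
#' of variation of the vineyard cohort, plus a cross-trait correlation matrix
#' for the Gaussian copula used by [sample_traits()]. [default_trait_spec()]
#' ships the 13 Barbera traits of the study vineyard: pre-dawn and mid-day
#' leaf water potential (MPa), total and lateral leaf area (m2/vine), pruning
#' weight and yield (kg/vine), cluster weight (g), berry weight (g), total
#' soluble solids (Brix), titratable acidity (g/L), must malate (g/L), total
#' anthocyanins and phenolics (mg/g).
#'
#' @param traits data.frame with columns `name`, `units`, `mean`, `min`,
#'   `max`, `cv_percent`. `min`/`max` are on the signed scale (so for water
#'   potential `min` is the most negative value).
#' @param correlation square correlation matrix (dimnames = trait names),
#'   symmetric positive semi-definite with unit diagonal, or `NULL` for
#'   independence.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(traits, correlation = NULL) {
  req <- c("name", "units", "mean", "min", "max", "cv_percent")
  if (!is.data.frame(traits) || !all(req %in% names(traits)))
    abort("traits must be a data.frame with columns name/units/mean/min/max/cv_percent",
          "invalid_spec")
  bad <- traits$min > traits$mean | traits$mean > traits$max
  if (any(bad))
    abort(paste("infeasible trait spec (need min <= mean <= max):",
                paste(traits$name[bad], collapse = ", ")), "invalid_spec")
  if (any(traits$cv_percent < 0))
    abort("cv_percent must be >= 0", "invalid_spec")
  if (is.null(correlation)) {
    correlation <- diag(nrow(traits))
    dimnames(correlation) <- list(traits$name, traits$name)
  }
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-12))
    abort("correlation must be symmetric with unit diagonal", "invalid_spec")
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8)
    abort("correlation matrix is not positive semi-definite", "invalid_spec")
  if (!identical(rownames(correlation), traits$name))
    abort("correlation dimnames must match trait names", "invalid_spec")
  structure(list(traits = traits, correlation = correlation),
            class = "trait_spec")
}

#' @rdname trait_spec
#' @export
default_trait_spec <- function() {
  traits <- data.frame(
    name = c("psi_pd", "psi_md", "tla", "lla", "pwt", "yield", "cwt", "bwt",
             "tss", "ta", "malate", "anth", "phenols"),
    units = c("MPa", "MPa", "m2/vine", "m2/vine", "kg/vine", "kg/vine", "g",
              "g", "Brix", "g/L", "g/L", "mg/g", "mg/g"),
    mean = c(-0.5, -1.34, 1.85, 0.17, 0.48, 3.37, 178.4, 2.0, 24.4, 9.66,
             2.13, 0.75, 1.78),
    min  = c(-0.73, -1.64, 0.65, 0.00, 0.16, 0.76, 54.3, 1.3, 19.0, 6.58,
             0.75, 0.18, 0.88),
    max  = c(-0.27, -1.08, 3.43, 0.53, 1.07, 8.46, 386.1, 2.8, 29.3, 14.41,
             5.99, 1.43, 2.71),
    cv_percent = c(24.2, 9.8, 33.8, 77.6, 48.7, 52.2, 41.6, 20.2, 11.4, 15.8,
                   56.8, 38.3, 26.0),
    stringsAsFactors = FALSE)
  trait_spec(traits, default_trait_correlation(traits$name))
}

#' Default cross-trait correlation matrix
#'
#' The study reports only marginal summaries, so the joint structure is a
#' modeling choice: vigor descriptors (leaf areas, pruning weight, yield
#' components) correlate positively with one another; pre-dawn water
#' potential correlates negatively with vigor (drier vines are smaller) and
#' positively with mid-day potential; malate, anthocyanins and phenolics move
#' together and against soluble solids; malate additionally tracks acidity
#' and (through canopy shading) vigor. Mild shrinkage toward zero is applied
#' if needed so the matrix is positive definite.
#'
#' @param names trait names in [default_trait_spec()] order.
#' @return Correlation matrix with `names` dimnames.
#' @export
default_trait_correlation <- function(names) {
  n <- length(names)
  R <- diag(n); dimnames(R) <- list(names, names)
  set_r <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  vigor <- c("tla", "lla", "pwt")
  for (i in seq_along(vigor)) for (j in seq_along(vigor))
    if (i < j) set_r(vigor[i], vigor[j], 0.55)
  set_r("yield", "cwt", 0.6); set_r("yield", "bwt", 0.4)
  set_r("cwt", "bwt", 0.45)
  for (v in vigor) {
    set_r(v, "yield", 0.4); set_r(v, "cwt", 0.3); set_r(v, "bwt", 0.25)
  }
  set_r("psi_pd", "psi_md", 0.5)
  for (v in c(vigor, "yield", "cwt", "bwt")) {
    set_r("psi_pd", v, -0.35); set_r("psi_md", v, -0.2)
  }
  qual <- c("malate", "anth", "phenols")
  for (i in seq_along(qual)) for (j in seq_along(qual))
    if (i < j) set_r(qual[i], qual[j], 0.4)
  for (q in qual) set_r("tss", q, -0.35)
  set_r("ta", "malate", 0.5); set_r("ta", "tss", -0.3)
  set_r("psi_pd", "malate", 0.3); set_r("psi_pd", "anth", -0.2)
  for (q in qual) { set_r("tla", q, if (q == "malate") 0.3 else 0.2) }
  # guarantee positive definiteness by shrinking off-diagonals if necessary
  shrink <- 1
  while (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    shrink <- shrink * 0.95
    R <- shrink * R; diag(R) <- 1
  }
  R
}

# Moments of the normal distribution truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  # far outside the window the mass collapses onto the nearer bound; return
  # that limit so root-finding over mu stays well-defined
  if (!is.finite(Z) || Z < 1e-300)
    return(c(mean = if (mu < (a + b) / 2) a else b, sd = 0))
  dal <- dnorm(al); dbe <- dnorm(be)
  m <- mu + sigma * (dal - dbe) / Z
  v <- sigma^2 * (1 + (al * dal - be * dbe) / Z - ((dal - dbe) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Quantile function of the truncated normal (vectorized in p).
truncnorm_quantile <- function(p, mu, sigma, a, b) {
  pa <- pnorm(a, mu, sigma); pb <- pnorm(b, mu, sigma)
  pmin(b, pmax(a, qnorm(pa + p * (pb - pa), mu, sigma)))
}

# Calibrate the parent (mu, sigma) of each truncated-normal marginal so the
# realized post-truncation mean equals the spec mean exactly and the sd is as
# close as possible to cv_percent/100 * |mean|. The mean is solved by a
# monotone 1-D root in mu for each candidate sigma; sigma is then a 1-D
# optimum. For a few highly skewed traits the target sd sits at the family
# boundary (sigma -> Inf approaches an exponential-tilt limit); sigma is
# capped at 30x the range and the nearest achievable sd is used.
calibrate_marginal <- function(m, s, a, b) {
  stopifnot(a < b, a <= m, m <= b)
  if (s == 0) return(list(mu = m, sigma = 0, mean = m, sd = 0))
  width <- b - a
  mu_for_mean <- function(sigma) {
    f <- function(mu) truncnorm_moments(mu, sigma, a, b)["mean"] - m
    lo <- a - 12 * sigma - width; hi <- b + 12 * sigma + width
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  sd_err <- function(log_sigma) {
    sigma <- exp(log_sigma)
    mu <- mu_for_mean(sigma)
    (truncnorm_moments(mu, sigma, a, b)["sd"] - s)^2
  }
  opt <- optimize(sd_err, interval = log(c(width * 1e-3, width * 30)),
                  tol = 1e-12)
  sigma <- exp(opt$minimum)
  mu <- mu_for_mean(sigma)
  mo <- truncnorm_moments(mu, sigma, a, b)
  list(mu = mu, sigma = sigma, mean = unname(mo["mean"]), sd = unname(mo["sd"]))
}

#' Calibrate a trait spec's truncated-normal marginals
#'
#' Solves, per trait, the parent normal parameters whose `[min, max]`
#' truncation reproduces the spec's mean exactly and its cv as closely as the
#' family allows (compensating the variance the truncation removes). The
#' result is cached on the spec so repeated sampling skips the solve.
#'
#' @param spec a [trait_spec()].
#' @return The spec with a `marginals` data.frame attached (columns `mu`,
#'   `sigma`, `achieved_mean`, `achieved_sd`).
#' @export
calibrate_trait_spec <- function(spec) {
  stopifnot(inherits(spec, "trait_spec"))
  if (!is.null(spec$marginals)) return(spec)
  tr <- spec$traits
  out <- lapply(seq_len(nrow(tr)), function(i) {
    s <- abs(tr$mean[i]) * tr$cv_percent[i] / 100
    calibrate_marginal(tr$mean[i], s, tr$min[i], tr$max[i])
  })
  spec$marginals <- data.frame(
    name = tr$name,
    mu = vapply(out, `[[`, numeric(1), "mu"),
    sigma = vapply(out, `[[`, numeric(1), "sigma"),
    achieved_mean = vapply(out, `[[`, numeric(1), "mean"),
    achieved_sd = vapply(out, `[[`, numeric(1), "sd"),
    stringsAsFactors = FALSE)
  spec
}

#' Draw a correlated synthetic trait table
#'
#' Samples `n` vines from a Gaussian copula over the calibrated
#' truncated-normal marginals: correlated standard-normal scores are mapped
#' through their probability integral transform into each trait's truncated
#' distribution, so every value respects the spec's `[min, max]` while
#' realized means and CVs converge to the spec targets at large `n`.
#' Deterministic for a fixed `(spec, n, seed)`.
#'
#' @param spec a [trait_spec()] (calibrated on the fly if needed).
#' @param n number of vines (>= 1).
#' @param seed integer seed; the global RNG stream is left untouched.
#' @return data.frame with `vine_id` plus one column per trait, attribute
#'   `units`.
#' @export
sample_traits <- function(spec, n, seed) {
  stopifnot(inherits(spec, "trait_spec"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    abort("n must be a positive integer", "invalid_argument")
  spec <- calibrate_trait_spec(spec)
  tr <- spec$traits
  p <- nrow(tr)
  L <- chol_psd(spec$correlation)
  Z <- with_seed(seed, matrix(rnorm(n * p), n, p) %*% L)
  U <- pnorm(Z)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, tr$name))
  for (j in seq_len(p)) {
    mj <- spec$marginals[j, ]
    X[, j] <- if (mj$sigma == 0) rep(tr$mean[j], n) else
      truncnorm_quantile(U[, j], mj$mu, mj$sigma, tr$min[j], tr$max[j])
  }
  out <- data.frame(vine_id = seq_len(n), X)
  attr(out, "units") <- stats::setNames(tr$units, tr$name)
  out
}

# Cholesky-like factor tolerant of semi-definite matrices.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' Summarize realized trait moments against the spec
#'
#' @param traits a table from [sample_traits()].
#' @param spec the generating [trait_spec()].
#' @return data.frame with realized and target mean / cv per trait.
#' @export
trait_calibration_summary <- function(traits, spec) {
  tr <- spec$traits
  realized_mean <- vapply(tr$name, function(nm) mean(traits[[nm]]), numeric(1))
  realized_sd <- vapply(tr$name, function(nm) sd(traits[[nm]]), numeric(1))
  data.frame(name = tr$name,
             target_mean = tr$mean, realized_mean = unname(realized_mean),
             target_cv = tr$cv_percent,
             realized_cv = unname(100 * realized_sd / abs(realized_mean)),
             stringsAsFactors = FALSE)
}
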