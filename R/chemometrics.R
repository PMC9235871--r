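#' Balanced random deletion groups for cross-validation
#'
#' Assigns each of `n` samples to one of `k` deletion groups, sizes
#' differing by at most one, as a pure function of `(n, k, seed)`.
#'
#' @param n number of samples.
#' @param k number of deletion groups (default 3).
#' @param seed integer seed.
#' @return An object of class `cv_plan`: list `n`, `k`, `seed`, `groups`
#'   (integer vector in 1..k).
#' @export
cv_plan <- function(n, k = 3, seed = 1) {
  if (k < 2 || k > n) abort("need 2 <= k <= n deletion groups", "plan_error")
  perm <- with_seed(seed, sample.int(n))
  groups <- integer(n)
  groups[perm] <- rep_len(seq_len(k), n)
  structure(list(n = n, k = k, seed = seed, groups = groups),
            class = "cv_plan")
}

#' Fit a mean-centered NIPALS PLS regression
#'
#' Classical single-response NIPALS with deflation: for each latent
#' variable, the weight vector is the covariance direction `X'y` (unit
#' norm), scores `t = Xw`, loadings `p = X't/t't`, response loading
#' `q = y't/t't`, then `X` and `y` are deflated by the rank-one score
#' contribution. Column means of `X` and the mean of `y` are stored and
#' applied to new data at prediction. With as many latent variables as the
#' (centered) rank of `X`, predictions coincide with ordinary least squares.
#'
#' @param X n x B predictor matrix (no missing values).
#' @param y response vector.
#' @param n_lv number of latent variables (1 <= n_lv <= min(n-1, B)).
#' @param center mean-center X and y before extraction (default TRUE; set
#'   FALSE when the data were already centered externally, e.g. under the
#'   global-centering cross-validation switch).
#' @return An object of class `pls_model` with scores `T`, weights `W`,
#'   loadings `P`, response loadings `q`, centering vectors and the
#'   regression vector `coef` (per LV count in `coef_by_lv`).
#' @export
fit_pls <- function(X, y, n_lv, center = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); B <- ncol(X)
  if (anyNA(X) || anyNA(y)) abort("missing values not allowed", "invalid_argument")
  if (length(y) != n) abort("length(y) must equal nrow(X)", "shape_error")
  if (n_lv < 1 || n_lv > min(n - 1, B))
    abort(sprintf("n_lv must lie in [1, %d]", min(n - 1, B)),
          "invalid_argument")
  x_center <- if (center) colMeans(X) else numeric(B)
  y_center <- if (center) mean(y) else 0
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  W <- P <- matrix(0, B, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  actual <- 0L
  for (h in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # response variance exhausted
    w <- w / nw
    th <- drop(Xc %*% w)
    tt <- sum(th^2)
    if (tt < 1e-24) break
    p <- drop(crossprod(Xc, th)) / tt
    qh <- sum(yc * th) / tt
    Xc <- Xc - tcrossprod(th, p)
    yc <- yc - th * qh
    W[, h] <- w; P[, h] <- p; Tm[, h] <- th; q[h] <- qh
    actual <- h
  }
  if (actual == 0L) abort("X carries no covariance with y", "invalid_argument")
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  Tm <- Tm[, seq_len(actual), drop = FALSE]
  q <- q[seq_len(actual)]
  # regression vectors in the original X coordinates, per LV count
  Rmat <- W %*% solve(t(P) %*% W)
  coef_by_lv <- sapply(seq_len(actual), function(a)
    Rmat[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  coef_by_lv <- matrix(coef_by_lv, nrow = B)
  structure(list(n_lv = actual, requested_lv = n_lv,
                 x_center = x_center, y_center = y_center,
                 W = W, P = P, T = Tm, q = q,
                 coef = coef_by_lv[, actual],
                 coef_by_lv = coef_by_lv),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a [fit_pls()] model.
#' @param newdata matrix of spectra (defaults to nothing; required).
#' @param n_lv number of latent variables to use (default: all fitted).
#' @param ... unused.
#' @return Vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  n_lv <- min(n_lv, object$n_lv)
  Xc <- sweep(as.matrix(newdata), 2, object$x_center)
  drop(Xc %*% object$coef_by_lv[, n_lv]) + object$y_center
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variable(s), %d bands\n",
              x$n_lv, length(x$x_center)))
  invisible(x)
}

#' Deletion-group cross-validation with LV selection
#'
#' For each deletion group the model (including centering) is refit on the
#' remaining samples and the left-out group predicted at every LV count up
#' to `lv_max`. RMSECV pools all held-out predictions; the chosen LV count
#' minimizes RMSECV (ties to fewer LVs). `r2_cv = 1 - PRESS/SS_tot` at the
#' chosen LV count (can be negative for models worse than the mean).
#'
#' @param X,y data.
#' @param lv_max maximum LV count to scan; reduced if a training fold is too
#'   small.
#' @param plan a [cv_plan()] covering all samples.
#' @param centering `"fold"` (default) refits the mean centering inside
#'   every training fold, avoiding leakage; `"global"` centers once on the
#'   full dataset before splitting, reproducing toolboxes that center the
#'   whole matrix up front.
#' @param r2_method `"press"` (default) defines `r2_cv = 1 - PRESS/SS_tot`;
#'   `"cor"` uses the squared correlation between held-out predictions and
#'   observations.
#' @return list `rmsecv` (per LV), `chosen_lv`, `r2_cv`, `cv_pred` (at the
#'   chosen LV count), `lv_max`.
#' @export
cross_validate <- function(X, y, lv_max, plan,
                           centering = c("fold", "global"),
                           r2_method = c("press", "cor")) {
  centering <- match.arg(centering)
  r2_method <- match.arg(r2_method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (!inherits(plan, "cv_plan") || plan$n != n)
    abort("plan does not cover the samples", "plan_error")
  if (min(table(plan$groups)) < 2)
    abort("every deletion group needs >= 2 samples", "plan_error")
  min_train <- n - max(table(plan$groups))
  lv_max <- min(lv_max, min_train - 1, ncol(X))
  if (lv_max < 1) abort("no feasible LV count for this plan", "plan_error")
  if (sd(y) == 0) {
    warning("constant response: cross-validated R2 undefined")
    return(list(rmsecv = rep(NA_real_, lv_max), chosen_lv = 1L,
                r2_cv = NA_real_, cv_pred = rep(y[1], n), lv_max = lv_max))
  }
  if (centering == "global") {
    Xf <- sweep(X, 2, colMeans(X)); yf <- y - mean(y)
    y_off <- mean(y)
  } else {
    Xf <- X; yf <- y; y_off <- 0
  }
  pred <- matrix(NA_real_, n, lv_max)
  for (g in seq_len(plan$k)) {
    hold <- plan$groups == g
    fit <- fit_pls(Xf[!hold, , drop = FALSE], yf[!hold], lv_max,
                   center = centering == "fold")
    for (a in seq_len(lv_max))
      pred[hold, a] <- predict(fit, Xf[hold, , drop = FALSE], n_lv = a) +
        y_off
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  chosen <- which.min(rmsecv)  # first minimum = fewer LVs on ties
  press <- sum((pred[, chosen] - y)^2)
  r2_cv <- if (r2_method == "press") 1 - press / sum((y - mean(y))^2)
    else stats::cor(pred[, chosen], y)^2
  list(rmsecv = rmsecv, chosen_lv = chosen, r2_cv = r2_cv,
       cv_pred = pred[, chosen], lv_max = lv_max)
}

#' Calibration + cross-validation performance of a PLS model
#'
#' Convenience wrapper: cross-validates to choose the LV count, refits on
#' all samples, and reports RMSEC, RMSECV, calibration and cross-validated
#' R-squared.
#'
#' @inheritParams cross_validate
#' @return list with `n_lv`, `rmsec`, `rmsecv`, `r2_cal`, `r2_cv`, `model`,
#'   `cv`.
#' @export
pls_performance <- function(X, y, lv_max, plan) {
  cv <- cross_validate(X, y, lv_max, plan)
  model <- fit_pls(X, y, cv$chosen_lv)
  fitted <- predict(model, X)
  rmsec <- sqrt(mean((fitted - y)^2))
  sst <- sum((y - mean(y))^2)
  r2_cal <- if (sst > 0) 1 - sum((fitted - y)^2) / sst else NA_real_
  list(n_lv = cv$chosen_lv, rmsec = rmsec,
       rmsecv = cv$rmsecv[cv$chosen_lv], r2_cal = r2_cal, r2_cv = cv$r2_cv,
       model = model, cv = cv)
}

# Partition 1..B into contiguous intervals of `width` bands; a remainder
# is absorbed into the last interval with a warning.
interval_partition <- function(B, width) {
  n_int <- B %/% width
  if (n_int < 1) abort("interval width exceeds band count", "invalid_argument")
  starts <- (seq_len(n_int) - 1) * width + 1
  ends <- starts + width - 1
  if (B %% width != 0) {
    warning(sprintf("%d bands not divisible by width %d: last interval absorbs the remainder",
                    B, width))
    ends[n_int] <- B
  }
  lapply(seq_len(n_int), function(i) starts[i]:ends[i])
}

#' Forward interval-PLS wavelength selection
#'
#' The spectrum is partitioned into contiguous intervals of `width` bands.
#' Selection starts from the single interval with the lowest RMSECV (LV
#' count re-optimized for every candidate set), then repeatedly adds the
#' interval whose inclusion most reduces RMSECV, stopping when no addition
#' strictly improves it. Ties break to the lower interval index.
#'
#' @param X,y data.
#' @param width interval width in bands (the study uses 10 and 5).
#' @param lv_max maximum LV count per candidate model.
#' @param plan a [cv_plan()].
#' @param grid optional band grid used to format selected ranges in nm.
#' @return An `ipls_result`: list with `width`, `partition`, `selected`
#'   (interval indices, sorted), `selected_bands` (column indices),
#'   `selected_ranges` (nm string, e.g. `"582:655 745:818"`), `trajectory`
#'   (RMSECV after each accepted step) and `performance`
#'   ([pls_performance()] on the selected bands).
#' @export
ipls_forward <- function(X, y, width, lv_max, plan, grid = NULL) {
  X <- as.matrix(X)
  part <- interval_partition(ncol(X), width)
  eval_set <- function(sel) {
    cols <- sort(unlist(part[sel]))
    cv <- cross_validate(X[, cols, drop = FALSE], y, lv_max, plan)
    cv$rmsecv[cv$chosen_lv]
  }
  scores <- vapply(seq_along(part), function(i) eval_set(i), numeric(1))
  selected <- which.min(scores)
  best <- scores[selected]
  trajectory <- best
  repeat {
    remaining <- setdiff(seq_along(part), selected)
    if (length(remaining) == 0) break
    cand <- vapply(remaining, function(i) eval_set(c(selected, i)),
                   numeric(1))
    i_best <- which.min(cand)  # lower interval index on ties
    if (cand[i_best] < best) {
      selected <- c(selected, remaining[i_best])
      best <- cand[i_best]
      trajectory <- c(trajectory, best)
    } else break
  }
  selected <- sort(selected)
  cols <- sort(unlist(part[selected]))
  perf <- pls_performance(X[, cols, drop = FALSE], y, lv_max, plan)
  structure(list(width = width, partition = part, selected = selected,
                 selected_bands = cols,
                 selected_ranges = format_ranges(selected, part, grid),
                 trajectory = trajectory, performance = perf),
            class = "ipls_result")
}

# "start:end start:end" nm ranges from selected intervals, merging adjacent
# intervals; falls back to band indices when no grid is given.
format_ranges <- function(selected, part, grid = NULL) {
  if (length(selected) == 0) return("")
  runs <- split(selected, cumsum(c(1, diff(selected) != 1)))
  fmt <- vapply(runs, function(r) {
    b0 <- min(part[[min(r)]]); b1 <- max(part[[max(r)]])
    if (is.null(grid)) sprintf("%d:%d", b0, b1)
    else sprintf("%d:%d", round(grid$centers[b0]), round(grid$centers[b1]))
  }, "")
  paste(fmt, collapse = " ")
}

#' @export
print.ipls_result <- function(x, ...) {
  cat(sprintf("ipls_result: width %d, selected %s (RMSECV %.4g, %d LV)\n",
              x$width, x$selected_ranges, x$performance$rmsecv,
              x$performance$n_lv))
  invisible(x)
}

#' Univariate index-trait regression table
#'
#' Ordinary least-squares regression of every trait on every vegetation
#' index, paired by `vine_id` (traits measured on a subset use only that
#' subset). Reports slope, intercept, R-squared, the two-sided p-value of
#' the slope F-test, and the significance class ladder
#' `p<0.0001 / p<0.001 / p<0.01 / ns`.
#'
#' @param vi_result data.frame from [compute_all_indices()].
#' @param traits trait table ([sample_traits()] layout).
#' @param min_n minimum paired observations per cell (default 3).
#' @return Long data.frame: `index`, `trait`, `n`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `class`.
#' @export
univariate_table <- function(vi_result, traits, min_n = 3) {
  idx_names <- setdiff(names(vi_result), "vine_id")
  trait_names <- setdiff(names(traits), "vine_id")
  m <- merge(vi_result, traits, by = "vine_id")
  rows <- vector("list", length(idx_names) * length(trait_names))
  r <- 0
  for (ix in idx_names) for (tr in trait_names) {
    r <- r + 1
    x <- m[[ix]]; y <- m[[tr]]
    ok <- stats::complete.cases(x, y)
    n_ok <- sum(ok)
    if (n_ok < min_n || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      if (n_ok >= min_n)
        warning(sprintf("zero variance in %s ~ %s: cell set to NA", tr, ix))
      rows[[r]] <- data.frame(index = ix, trait = tr, n = n_ok,
                              slope = NA_real_, intercept = NA_real_,
                              r_squared = NA_real_, p_value = NA_real_,
                              class = NA_character_)
      next
    }
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE)
    rows[[r]] <- data.frame(index = ix, trait = tr, n = n_ok,
                            slope = unname(coef(fit)[2]),
                            intercept = unname(coef(fit)[1]),
                            r_squared = sm$r.squared, p_value = unname(p),
                            class = significance_class(p))
  }
  do.call(rbind, rows)
}

# The footnote ladder: four classes bounded at 0.0001 / 0.001 / 0.01.
significance_class <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "p<0.0001" else if (p < 1e-3) "p<0.001"
  else if (p < 1e-2) "p<0.01" else "ns"
}

#' Pivot a univariate table into index x trait matrices
#'
#' @param uni a [univariate_table()] result.
#' @param value `"r_squared"` or `"class"`.
#' @return data.frame, indices as rows, traits as columns.
#' @export
univariate_matrix <- function(uni, value = c("r_squared", "class")) {
  value <- match.arg(value)
  idx <- unique(uni$index); tr <- unique(uni$trait)
  out <- matrix(if (value == "class") NA_character_ else NA_real_,
                length(idx), length(tr), dimnames = list(idx, tr))
  for (i in seq_len(nrow(uni)))
    out[uni$index[i], uni$trait[i]] <- uni[[value]][i]
  data.frame(index = idx, out, check.names = FALSE, row.names = NULL)
}

#' Full-spectrum PLS and forward iPLS report for every trait
#'
#' For each trait (pairing by `vine_id`, dropping missing values so traits
#' measured on a subset use only that subset): one full-spectrum PLS row
#' and one forward-iPLS row per interval width. Within each trait, the best
#' row minimizes RMSECV, ties broken by higher cross-validated R-squared
#' and then by fewer selected variables.
#'
#' @param ds a [spectral_dataset()].
#' @param traits trait table.
#' @param lv_max maximum LV count (default `min(10, floor(n/3))` per trait).
#' @param k number of deletion groups.
#' @param seed seed for the cross-validation plans.
#' @param widths iPLS interval widths.
#' @return data.frame: `trait`, `method`, `interval_size`, `selected_bands`,
#'   `n_vars`, `lvs`, `rmsec`, `rmsecv`, `r2_cal`, `r2_cv`, `best`.
#' @export
build_model_report <- function(ds, traits, lv_max = NULL, k = 3, seed = 1,
                               widths = c(10, 5)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  trait_names <- setdiff(names(traits), "vine_id")
  rows <- list()
  for (tr in trait_names) {
    y_all <- traits[[tr]][match(ds$vine_id, traits$vine_id)]
    ok <- !is.na(y_all)
    X <- ds$spectra[ok, , drop = FALSE]
    y <- y_all[ok]
    n <- length(y)
    lvm <- lv_max %||% min(10, n %/% 3)
    plan <- cv_plan(n, k, seed)
    perf <- pls_performance(X, y, lvm, plan)
    rows[[length(rows) + 1]] <- data.frame(
      trait = tr, method = "PLS", interval_size = NA_integer_,
      selected_bands = "", n_vars = ncol(X), lvs = perf$n_lv,
      rmsec = perf$rmsec, rmsecv = perf$rmsecv, r2_cal = perf$r2_cal,
      r2_cv = perf$r2_cv)
    for (w in widths) {
      ip <- ipls_forward(X, y, w, lvm, plan, grid = ds$grid)
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, method = "iPLS", interval_size = w,
        selected_bands = ip$selected_ranges,
        n_vars = length(ip$selected_bands), lvs = ip$performance$n_lv,
        rmsec = ip$performance$rmsec, rmsecv = ip$performance$rmsecv,
        r2_cal = ip$performance$r2_cal, r2_cv = ip$performance$r2_cv)
    }
  }
  rep <- do.call(rbind, rows)
  rep$best <- FALSE
  for (tr in trait_names) {
    i <- which(rep$trait == tr)
    o <- order(rep$rmsecv[i], -rep$r2_cv[i], rep$n_vars[i])
    rep$best[i[o[1]]] <- TRUE
  }
  rep
}
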