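test_that("deletion groups are balanced and a pure function of the seed", {
  p <- cv_plan(30, 3, seed = 4)
  expect_equal(unname(table(p$groups)), rep(10L, 3), ignore_attr = TRUE)
  expect_identical(p, cv_plan(30, 3, seed = 4))
  expect_false(identical(p$groups, cv_plan(30, 3, seed = 5)$groups))
  p2 <- cv_plan(31, 3, seed = 1)
  expect_lte(diff(range(table(p2$groups))), 1)
  expect_error(cv_plan(5, 6), class = "plan_error")
})

test_that("PLS collapses to simple regression on one predictor", {
  set.seed(21)
  x <- matrix(rnorm(15), 15, 1)
  y <- 2 * x[, 1] + rnorm(15)
  m <- fit_pls(x, y, 1)
  expect_equal(predict(m, x), unname(fitted(lm(y ~ x))), tolerance = 1e-10)
})

test_that("PLS with all LVs on full-rank X equals the least-squares oracle", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(20 * 5), 20, 5)
    y <- rnorm(20)
    m <- fit_pls(X, y, 5)
    ols <- unname(lm.fit(cbind(1, X), y)$fitted.values)
    expect_lt(max(abs(predict(m, X) - ols)), 1e-6)
  }
})

test_that("successive latent-variable scores are mutually orthogonal", {
  set.seed(22)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rnorm(40)
  m <- fit_pls(X, y, 6)
  G <- crossprod(m$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("a noiseless 3-band signal on orthogonal bands needs <= 3 LVs", {
  # With mutually orthogonal (mean-zero) predictor columns of distinct
  # norms, the PLS Krylov space reaches the 3-sparse coefficient vector in
  # exactly 3 components; correlated predictors generally need more.
  set.seed(23)
  M <- scale(matrix(rnorm(30 * 10), 30, 10), scale = FALSE)
  Q <- qr.Q(qr(M))                      # orthonormal, mean-zero columns
  X <- Q %*% diag(seq(1, 4, length.out = 10))
  b <- numeric(10); b[c(2, 5, 9)] <- c(1, -2, 0.5)
  y <- as.numeric(X %*% b)
  sst <- sum((y - mean(y))^2)
  r2 <- function(m) 1 - sum((predict(m, X) - y)^2) / sst
  expect_gt(r2(fit_pls(X, y, 3)), 1 - 1e-8)
  expect_lt(r2(fit_pls(X, y, 2)), 1 - 1e-8)
})

test_that("our NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(24)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("b", 1:10)))
  y <- as.numeric(X %*% rnorm(10) + 0.5 * rnorm(30))
  theirs <- mixOmics::pls(X, data.frame(y = y), ncomp = 3,
                          mode = "regression", scale = FALSE)
  pred_theirs <- predict(theirs, X)$predict[, , 3]
  pred_ours <- predict(fit_pls(X, y, 3), X)
  expect_lt(max(abs(pred_theirs - pred_ours)), 1e-8)
})

test_that("invalid LV counts and missing values are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rnorm(10), 0), class = "invalid_argument")
  expect_error(fit_pls(X, rnorm(10), 5), class = "invalid_argument")
  X[1, 1] <- NA
  expect_error(fit_pls(X, rnorm(10), 1), class = "invalid_argument")
})

test_that("cross-validation pools held-out predictions per LV count", {
  set.seed(25)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- as.numeric(X[, 1] - X[, 5] + 0.2 * rnorm(30))
  plan <- cv_plan(30, 3, seed = 1)
  cv <- cross_validate(X, y, 5, plan)
  expect_length(cv$rmsecv, 5)
  expect_equal(cv$chosen_lv, which.min(cv$rmsecv))
  # RMSECV is invariant to sample order given the same plan
  perm <- sample(30)
  plan_p <- plan; plan_p$groups <- plan$groups[perm]
  cv_p <- cross_validate(X[perm, ], y[perm], 5, plan_p)
  expect_equal(cv_p$rmsecv, cv$rmsecv, tolerance = 1e-12)
  # r2_cv is 1 - PRESS/SS_tot
  press <- sum((cv$cv_pred - y)^2)
  expect_equal(cv$r2_cv, 1 - press / sum((y - mean(y))^2))
})

test_that("centering and r2 definition switches behave as documented", {
  set.seed(30)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- as.numeric(X[, 2] + 0.3 * rnorm(30))
  plan <- cv_plan(30, 3, seed = 2)
  fold <- cross_validate(X, y, 4, plan)
  glob <- cross_validate(X, y, 4, plan, centering = "global")
  # both are valid estimators and should be close, not identical
  expect_false(identical(fold$rmsecv, glob$rmsecv))
  expect_equal(fold$rmsecv, glob$rmsecv, tolerance = 0.2)
  # squared-correlation R2 is never below the PRESS-based definition here
  r2c <- cross_validate(X, y, 4, plan, r2_method = "cor")
  expect_gte(r2c$r2_cv, fold$r2_cv - 1e-12)
  # uncentered fit on pre-centered data equals the centered fit
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  m1 <- fit_pls(X, y, 3)
  m2 <- fit_pls(Xc, yc, 3, center = FALSE)
  expect_equal(predict(m2, Xc) + mean(y), predict(m1, X),
               tolerance = 1e-10)
})

test_that("constant responses cross-validate to NA with a warning", {
  X <- matrix(rnorm(30 * 5), 30, 5)
  expect_warning(cv <- cross_validate(X, rep(2, 30), 3, cv_plan(30, 3, 1)),
                 "constant response")
  expect_true(is.na(cv$r2_cv))
})

test_that("calibration R2 is monotone non-decreasing in the LV count", {
  set.seed(26)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- as.numeric(X %*% rnorm(10) + rnorm(25))
  sst <- sum((y - mean(y))^2)
  m <- fit_pls(X, y, 8)
  r2 <- vapply(1:8, function(a)
    1 - sum((predict(m, X, n_lv = a) - y)^2) / sst, numeric(1))
  expect_true(all(diff(r2) > -1e-12))
})

test_that("interval partitions follow the declared widths", {
  expect_length(interval_partition(50, 10), 5)
  expect_length(interval_partition(50, 5), 10)
  expect_warning(p <- interval_partition(50, 8), "remainder")
  expect_length(p, 6)
  expect_equal(p[[6]], 41:50)
})

test_that("forward iPLS stops after one interval on pure noise", {
  set.seed(27)
  X <- matrix(rnorm(60 * 50), 60, 50)
  y <- rnorm(60)
  ip <- ipls_forward(X, y, 10, 5, cv_plan(60, 3, 2))
  expect_length(ip$selected, 1)
  expect_length(ip$trajectory, 1)
})

test_that("the iPLS trajectory decreases strictly until the stop", {
  set.seed(28)
  X <- matrix(rnorm(60 * 50), 60, 50)
  b <- numeric(50); b[12:25] <- 1
  y <- as.numeric(X %*% b + 0.1 * sd(X %*% b) * rnorm(60))
  ip <- ipls_forward(X, y, 10, 10, cv_plan(60, 3, 3), default_grid)
  expect_true(all(diff(ip$trajectory) < 0))
  expect_true(all(ip$selected %in% seq_along(ip$partition)))
  # selected nm ranges merge adjacent intervals
  expect_match(ip$selected_ranges, "^\\d+:\\d+( \\d+:\\d+)*$")
})

test_that("univariate table: perfect line, significance ladder, shapes", {
  vi <- data.frame(vine_id = 1:10, IDX = 1:10 / 10)
  tr <- data.frame(vine_id = 1:10, trait = 2 * (1:10 / 10) + 1)
  u <- suppressWarnings(univariate_table(vi, tr))  # lm's perfect-fit note
  expect_equal(u$r_squared, 1)
  expect_equal(u$slope, 2)
  expect_equal(u$intercept, 1)
  expect_equal(u$class, "p<0.0001")
  # subset pairing: trait measured on 5 of 10 vines
  tr2 <- tr; tr2$trait[6:10] <- NA
  u2 <- suppressWarnings(univariate_table(vi, tr2))
  expect_equal(u2$n, 5)
  # zero-variance column gives an NA cell with warning
  vi0 <- data.frame(vine_id = 1:10, IDX = 0.5)
  expect_warning(u0 <- univariate_table(vi0, tr), "zero variance")
  expect_true(is.na(u0$r_squared))
  expect_equal(significance_class(0.005), "p<0.01")
  expect_equal(significance_class(0.5), "ns")
  expect_equal(significance_class(5e-4), "p<0.001")
})

test_that("independent index and trait give ~1% false positives at p<0.01", {
  set.seed(29)
  vi <- data.frame(vine_id = 1:30, matrix(rnorm(30 * 50), 30, 50,
                                          dimnames = list(NULL, paste0("idx", 1:50))))
  tr <- data.frame(vine_id = 1:30, matrix(rnorm(30 * 30), 30, 30,
                                          dimnames = list(NULL, paste0("tr", 1:30))))
  u <- univariate_table(vi, tr)
  expect_equal(nrow(u), 1500)
  frac <- mean(u$p_value < 0.01)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / 1500))
  expect_true(all((u$p_value < 0.01) == (u$class != "ns")))
})

test_that("the model report has 3 rows per trait and a deterministic best", {
  tr <- sample_traits(default_trait_spec(), 30, seed = 8)[
    , c("vine_id", "psi_pd", "malate")]
  ds <- canopy_reflectance(tr_full <- sample_traits(default_trait_spec(),
                                                    30, seed = 8),
                           default_grid, seed = 8)
  rep1 <- build_model_report(ds, tr, seed = 3)
  expect_equal(nrow(rep1), 2 * 3)
  expect_equal(sum(rep1$best[rep1$trait == "psi_pd"]), 1)
  expect_equal(sum(rep1$best[rep1$trait == "malate"]), 1)
  # determinism
  rep2 <- build_model_report(ds, tr, seed = 3)
  expect_identical(rep1, rep2)
  # best row attains the trait-wise minimum RMSECV
  for (t in c("psi_pd", "malate")) {
    sub <- rep1[rep1$trait == t, ]
    expect_equal(sub$rmsecv[sub$best], min(sub$rmsecv))
  }
})
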