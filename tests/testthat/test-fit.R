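test_that("design width matches the published model layouts", {
  s <- test_series(seed = 1L, n_days = 730L)
  cb <- crossbasis(s$temp_mean, 14, 6, 4)
  d1 <- build_design(s, cb)
  # intercept + 6x4 cross-basis + 24 time + 6 dow = 55
  expect_equal(ncol(d1$X) + 1L, 55L)
  d2 <- build_design(s, cb, linear = c("tv", "pm25", "so2"),
                     smooth = list(rh = 3))
  expect_equal(ncol(d2$X) + 1L, 61L)
  # the mask drops exactly the first 14 rows when covariates are complete
  expect_equal(which(!d1$mask), 1:14)
  expect_error(build_design(s, cb, linear = "nope"), "not found")
})

test_that("rank deficiency is reported with the offending block", {
  s <- test_series(seed = 1L, n_days = 200L)
  s$dup <- s$tv
  cb <- crossbasis(s$temp_mean, 7, 3, 2)
  expect_error(build_design(s, cb, linear = c("tv", "dup")),
               "rank deficient in block 'dup'")
})

test_that("closed-form Poisson fits: intercept-only and binary covariate", {
  f <- fit_poisson(c(1, 2, 3), matrix(numeric(0), 3, 0))
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-9)
  expect_equal(unname(f$fitted), rep(2, 3), tolerance = 1e-9)

  g <- rep(0:1, each = 4)
  y <- c(2, 4, 3, 3, 8, 12, 10, 10)   # means 3 and 10
  f2 <- fit_poisson(y, cbind(g = g))
  expect_equal(unname(f2$coefficients), c(log(3), log(10 / 3)),
               tolerance = 1e-9)
})

test_that("IRLS coefficients match direct likelihood maximization", {
  set.seed(21)
  X <- cbind(rnorm(50), runif(50), rbinom(50, 1, 0.4))
  y <- rpois(50, exp(1 + X %*% c(0.3, -0.5, 0.2)))
  f <- fit_poisson(y, X)
  expect_lt(max(abs(unname(f$coefficients) - brute_poisson_fit(y, X))),
            1e-6)
  # score equations hold at the optimum
  expect_lt(max(abs(crossprod(cbind(1, X), y - f$fitted))), 1e-6)
  # AIC is the definition, with the full log-likelihood
  expect_equal(f$aic, -2 * sum(dpois(y, f$fitted, log = TRUE)) + 2 * 4)
})

test_that("quasipoisson inflates the covariance by the dispersion", {
  set.seed(22)
  X <- cbind(rnorm(80))
  y <- rpois(80, exp(2 + 0.3 * X[, 1L]))
  fp <- fit_poisson(y, X, family = "poisson")
  fq <- fit_poisson(y, X, family = "quasipoisson")
  expect_equal(fq$coefficients, fp$coefficients)
  expect_equal(fq$vcov, fp$vcov * fp$dispersion, tolerance = 1e-12)
})

test_that("dispersion: zero at a saturated mean, ~1 Poisson, >1 NB", {
  y0 <- rep(5L, 20L)
  expect_equal(dispersion(fit_poisson(y0, matrix(numeric(0), 20, 0))), 0,
               tolerance = 1e-12)
  set.seed(23)
  y1 <- rpois(5000, 7)
  expect_equal(dispersion(fit_poisson(y1, matrix(numeric(0), 5000, 0))),
               1, tolerance = 0.1)
  y2 <- rnbinom(5000, size = 7, mu = 7)   # variance 2 * mu
  expect_gt(dispersion(fit_poisson(y2, matrix(numeric(0), 5000, 0))), 1.5)
})

test_that("score equations hold for the full DLNM design", {
  s <- test_series(seed = 2L, n_days = 400L)
  fit <- dlnm_fit(s, covariates = multi_covariates)
  cb <- crossbasis(s$temp_mean, 14, 6, 4)
  d <- build_design(s, cb, linear = c("tv", "pm25", "so2"),
                    smooth = list(rh = 3))
  Xi <- cbind(1, d$X[d$mask, ])
  expect_lt(max(abs(crossprod(Xi, d$y[d$mask] - fit$fitted[d$mask]))),
            1e-6)
  expect_equal(fit$n_used, sum(d$mask))
})

test_that("RR contrasts are invariant to nuisance parameterizations", {
  s <- test_series(seed = 2L, n_days = 400L)
  fit <- dlnm_fit(s, covariates = multi_covariates)
  rr <- suppressWarnings(lag_rr(fit, -5, lag = 7)$rr)

  # affine rescaling of a linear covariate
  s2 <- as.data.frame(s)
  s2$pm25 <- s2$pm25 / 10 + 5
  fit2 <- dlnm_fit(daily_series(s2), covariates = multi_covariates)
  expect_equal(suppressWarnings(lag_rr(fit2, -5, lag = 7)$rr), rr,
               tolerance = 1e-8)

  # day-of-week reference category
  cb <- fit$crossbasis
  d <- build_design(s, cb, linear = c("tv", "pm25", "so2"),
                    smooth = list(rh = 3))
  X_alt <- d$X
  dow_cols <- grep("^dow", colnames(X_alt))
  X_alt <- cbind(X_alt[, -dow_cols], dow_dummies(s$date, reference = "Thu"))
  f_alt <- fit_poisson(d$y[d$mask], X_alt[d$mask, ])
  idx <- fit$term_index$crossbasis
  cc <- suppressWarnings(contrast_vector(cb, -5, fit$ref, 7))
  expect_equal(unname(sum(cc * f_alt$coefficients[idx])),
               unname(sum(cc * fit$coefficients[idx])), tolerance = 1e-8)
})

test_that("row-permuted refits reproduce the coefficients", {
  set.seed(24)
  X <- cbind(rnorm(60), runif(60))
  y <- rpois(60, exp(2 + X %*% c(0.2, -0.3)))
  f <- fit_poisson(y, X)
  perm <- sample.int(60L)
  f2 <- fit_poisson(y[perm], X[perm, ])
  expect_equal(f2$coefficients, f$coefficients, tolerance = 1e-9)
})

test_that("df selection: degenerate grid, AIC definition, recovery", {
  s <- test_series(seed = 3L, n_days = 300L)
  one <- select_df(s, 4L, 3L)
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$exposure_df, 4L)
  expect_equal(one$lag_df, 3L)
  expect_equal(one$table$aic[1L],
               -2 * one$fit$loglik + 2 * length(one$fit$coefficients))

  # data carrying a genuine (6,4) cross-basis signal: the AIC-minimal
  # model recovers (6,4) over a {4,6} x {2,4} grid in most replicates
  env <- generate_environment(seed = 99L, n_days = 400L)
  cb <- crossbasis(env$temp_mean, 14, 6, 4)
  hits <- 0L
  n_rep <- 25L
  set.seed(77)
  for (r in seq_len(n_rep)) {
    beta <- rnorm(24, 0, 0.12)
    eta <- 3 + as.vector(cb$matrix %*% beta)
    df <- as.data.frame(env)
    df$stroke <- NA_integer_
    ok <- !is.na(eta)
    df$stroke[ok] <- rpois(sum(ok), exp(pmin(eta[ok], 8)))
    df$stroke[!ok] <- 0L
    sel <- select_df(daily_series(df), c(4L, 6L), c(2L, 4L))
    hits <- hits + (sel$exposure_df == 6L && sel$lag_df == 4L)
  }
  expect_gt(hits / n_rep, 0.5)
})

test_that("fit methods behave like standard modelling objects", {
  s <- test_series(seed = 1L, n_days = 400L)
  fit <- dlnm_fit(s, covariates = multi_covariates)
  expect_s3_class(fit, "dlnm_fit")
  expect_output(print(fit), "Distributed lag")
  expect_equal(AIC(logLik(fit)), fit$aic)
  expect_length(coef(fit), nrow(vcov(fit)))
  expect_equal(length(residuals(fit)), fit$n_used)
  expect_equal(mean(residuals(fit, type = "response")), 0,
               tolerance = 1e-6)
  sm <- summary(fit)
  expect_true(all(c("tv", "pm25", "so2") %in% rownames(sm$coef_table)))
  set.seed(1)
  sims <- simulate(fit, nsim = 2L)
  expect_equal(dim(sims), c(nrow(s), 2L))
  expect_true(all(is.na(sims$sim_1[1:14])))
})
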