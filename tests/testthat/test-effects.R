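fit_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$fit))
      env$fit <- dlnm_fit(test_series(seed = 4L, n_days = 400L),
                          covariates = multi_covariates)
    env$fit
  }
})

test_that("the reference temperature maps to RR 1 with a degenerate CI", {
  fit <- fit_cache()
  s <- predict(fit, temps = fit$ref)
  expect_equal(unname(s$rr[1L, ]), rep(1, 15))
  expect_equal(unname(s$se[1L, ]), rep(0, 15))
  expect_equal(unname(s$lo[1L, ]), rep(1, 15))
  expect_equal(unname(s$hi[1L, ]), rep(1, 15))
})

test_that("zero cross-basis coefficients give RR 1 everywhere", {
  fit <- fit_cache()
  fit0 <- fit
  fit0$coefficients[fit0$term_index$crossbasis] <- 0
  s <- suppressWarnings(predict(fit0, temps = c(-10, 0, 25, 30)))
  expect_equal(unname(s$rr), matrix(1, 4, 15))
  tabs <- suppressWarnings(effect_tables(fit0))
  expect_true(all(tabs$lag_specific$rr == 1))
  expect_true(all(tabs$cumulative$rr == 1))
  expect_false(any(tabs$lag_specific$significant))
  expect_false(any(tabs$cumulative$significant))
})

test_that("delta-method se matches Monte-Carlo over coefficient draws", {
  fit <- fit_cache()
  idx <- fit$term_index$crossbasis
  V <- fit$vcov[idx, idx]
  beta <- fit$coefficients[idx]
  Lc <- chol(V)
  set.seed(123)
  Z <- matrix(rnorm(2e5 * length(beta)), 2e5)
  draws <- Z %*% Lc                       # centered draws of the cb block
  pts <- list(c(-6, 3L), c(24, 10L))
  for (p in pts) {
    cc <- contrast_vector(fit$crossbasis, p[1L], fit$ref, p[2L])
    mc_sd <- sd(draws %*% cc)
    r <- lag_rr(fit, p[1L], lag = p[2L])
    expect_equal(r$se, mc_sd, tolerance = 0.01)
  }
  # cumulative contrast variance, same oracle
  ccum <- cumulative_contrast(fit$crossbasis, -6, fit$ref, c(0, 14))
  r <- cumulative_rr(fit, -6, window = c(0, 14))
  expect_gte(r$se, 0)
  expect_equal(r$se, sd(draws %*% ccum), tolerance = 0.01)
})

test_that("cumulative log-RR identities hold", {
  fit <- fit_cache()
  x <- -4
  # single-lag window equals the lag-specific estimate
  expect_equal(cumulative_rr(fit, x, window = c(5, 5)),
               lag_rr(fit, x, lag = 5L))
  # (0,14) equals the sum of the 15 single-lag log-RRs
  lags <- vapply(0:14, function(l) lag_rr(fit, x, lag = l)$log_rr,
                 numeric(1L))
  expect_equal(cumulative_rr(fit, x, window = c(0, 14))$log_rr, sum(lags),
               tolerance = 1e-10)
  # window nesting: (0,14) = (0,10) + (11,14)
  expect_equal(cumulative_rr(fit, x, window = c(0, 14))$log_rr,
               cumulative_rr(fit, x, window = c(0, 10))$log_rr +
                 cumulative_rr(fit, x, window = c(11, 14))$log_rr,
               tolerance = 1e-10)
})

test_that("log-RR differences are independent of the reference", {
  fit <- fit_cache()
  s1 <- predict(fit, temps = c(-5, 20), ref = fit$ref)
  s2 <- predict(fit, temps = c(-5, 20), ref = 5)
  d1 <- s1$log_rr[1L, ] - s1$log_rr[2L, ]
  d2 <- s2$log_rr[1L, ] - s2$log_rr[2L, ]
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("confidence intervals use z = 1.959964 and widen with level", {
  fit <- fit_cache()
  r95 <- lag_rr(fit, -4, lag = 8L)
  expect_equal(log(r95$hi) - r95$log_rr, 1.959964 * r95$se,
               tolerance = 1e-6)
  r99 <- lag_rr(fit, -4, lag = 8L, level = 0.99)
  expect_gt(r99$hi - r99$lo, r95$hi - r95$lo)
})

test_that("minimum-risk temperature: ref invariance and strong recovery", {
  fit <- fit_cache()
  m1 <- find_mmt(fit)
  m2 <- find_mmt(fit, ref = quantile_cutpoints(fit$temp, 0.25))
  expect_equal(m1, m2)
  # a long, strong-signal series pins the hinge down tightly
  strong <- simulate_stroke_series(
    seed = 11L, n_days = 1460L,
    surface = true_surface(cold_rr = 1.5, cold_cum_rr = 4, hot_rr = 1.4))
  fs <- dlnm_fit(strong, covariates = multi_covariates)
  expect_lt(abs(find_mmt(fs) - 17), 2)
})

test_that("a monotone risk curve returns the grid boundary with a warning", {
  fit <- fit_cache()
  fit_mono <- fit
  idx <- fit$term_index$crossbasis
  # coefficients proportional to a monotone exposure shape: project the
  # identity function onto the exposure basis, uniform over lags
  cbx <- fit$crossbasis
  xs <- seq(cbx$exposure_range[1L], cbx$exposure_range[2L], length.out = 80)
  Bx <- templag:::eval_basis(cbx$exposure_spec, xs)
  u <- qr.solve(Bx, xs - mean(xs))
  v <- qr.solve(cbx$lag_basis, rep(1 / 15, 15))
  fit_mono$coefficients[idx] <- kronecker(-u, v) * 0.01
  expect_warning(m <- find_mmt(fit_mono), "monotone")
  grid <- seq(quantile_cutpoints(fit$temp, 0.05),
              quantile_cutpoints(fit$temp, 0.95), by = 0.1)
  expect_true(m %in% range(grid))
})

test_that("effect tables have the published shape and self-consistent cells", {
  fit <- fit_cache()
  tabs <- suppressWarnings(effect_tables(fit))
  expect_equal(nrow(tabs$lag_specific), 4L * 15L)
  expect_equal(nrow(tabs$cumulative), 4L * 4L)
  cell <- tabs$cumulative[tabs$cumulative$label == "extreme_cold" &
                            tabs$cumulative$l1 == 14L, ]
  direct <- suppressWarnings(
    cumulative_rr(fit, unname(fit$cutpoints["p1"]), window = c(0, 14)))
  expect_equal(cell$rr, direct$rr)
  expect_equal(cell$lo, direct$lo)
  lag_cell <- tabs$lag_specific[tabs$lag_specific$label == "extreme_hot" &
                                  tabs$lag_specific$lag == 6L, ]
  expect_equal(lag_cell$rr,
               suppressWarnings(
                 lag_rr(fit, unname(fit$cutpoints["p99"]), lag = 6L)$rr))
})

test_that("surface and fit plots render without error", {
  fit <- fit_cache()
  s <- predict(fit, temps = seq(-8, 30, by = 1))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error({
    plot(s, type = "overall")
    plot(s, type = "lag", at = c(-8, 28))
    plot(s, type = "contour")
    plot(fit)
  })
  grDevices::dev.off()
})
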