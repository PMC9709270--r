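#' Day-of-week indicator block
#'
#' Six dummy columns coding the day of week of each date, with Monday as
#' the all-zero reference category. Relative-risk contrasts from the fitted
#' model are invariant to the reference choice.
#'
#' @param dates a `Date` vector.
#' @param reference reference day name (default `"Mon"`).
#' @return an `n x 6` 0/1 matrix with columns `dow<Day>`.
#' @export
dow_dummies <- function(dates, reference = "Mon") {
  days <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
  stopifnot(reference %in% days)
  wd <- days[as.POSIXlt(dates)$wday + 1L]
  lev <- c(reference, setdiff(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat",
                                "Sun"), reference))
  f <- factor(wd, levels = lev)
  out <- matrix(0, length(dates), 6L,
                dimnames = list(NULL, paste0("dow", lev[-1L])))
  for (j in 2:7) out[f == lev[j], j - 1L] <- 1
  out
}

#' Assemble the regression design for a DLNM fit
#'
#' Builds the response and design matrix
#' `[cross-basis | linear terms | smooth terms | time spline | day-of-week]`
#' (the intercept is added by the fitter) along with a row mask excluding
#' incomplete cross-basis rows and rows with missing data.
#'
#' @param series a [daily_series()].
#' @param cb a [crossbasis()] built from `series$temp_mean`.
#' @param outcome name of the count column to model.
#' @param linear names of covariates entering linearly.
#' @param smooth named list of spline df for covariates entering as natural
#'   spline smooths, e.g. `list(rh = 3)`.
#' @param time_df_per_year df per year for the long-term/seasonality spline
#'   on the day index (total df = `round(time_df_per_year * n / 365.25)`).
#' @return a list with `y`, `X`, `mask` (logical rows used), and
#'   `term_index` (named list of column indices per block, offset to match
#'   the coefficient vector of [fit_poisson()], whose first element is the
#'   intercept).
#' @export
build_design <- function(series, cb, outcome = "stroke",
                         linear = character(), smooth = list(),
                         time_df_per_year = 12) {
  stopifnot(inherits(series, "daily_series"), inherits(cb, "crossbasis"))
  if (!outcome %in% names(series))
    stop("outcome column '", outcome, "' not found")
  miss <- setdiff(c(linear, names(smooth)), names(series))
  if (length(miss))
    stop("covariate(s) not found in series: ", paste(miss, collapse = ", "))
  n <- nrow(series)
  y <- series[[outcome]]

  blocks <- list(crossbasis = cb$matrix)
  for (v in linear) {
    m <- matrix(series[[v]], ncol = 1L, dimnames = list(NULL, v))
    blocks[[v]] <- m
  }
  for (v in names(smooth)) {
    b <- natural_spline_basis(series[[v]], basis_spec(smooth[[v]]))
    colnames(b) <- paste0(v, "_ns", seq_len(ncol(b)))
    blocks[[paste0(v, "_ns")]] <- b
  }
  time_df <- max(2L, as.integer(round(time_df_per_year * n / 365.25)))
  tb <- natural_spline_basis(series$t, basis_spec(time_df))
  colnames(tb) <- paste0("time_ns", seq_len(ncol(tb)))
  blocks$time_ns <- tb
  blocks$dow <- dow_dummies(series$date)

  X <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1L))
  ends <- cumsum(sizes)
  term_index <- Map(function(e, s) (e - s + 1L):e + 1L, ends, sizes)

  mask <- !is.na(y) & stats::complete.cases(X)
  check_design_rank(X, mask, sizes)
  list(y = y, X = X, mask = mask, term_index = term_index)
}

check_design_rank <- function(X, mask, sizes) {
  Xm <- cbind(1, X[mask, , drop = FALSE])
  r <- qr(Xm)$rank
  if (r == ncol(Xm)) return(invisible(NULL))
  ends <- cumsum(sizes) + 1L
  prev <- 1L
  for (i in seq_along(sizes)) {
    ri <- qr(Xm[, 1:ends[i], drop = FALSE])$rank
    if (ri < prev + sizes[i])
      stop("design is rank deficient in block '", names(sizes)[i], "'")
    prev <- ri
  }
  stop("design is rank deficient")
}

#' Poisson log-linear fit by iteratively reweighted least squares
#'
#' Maximises the Poisson log-likelihood with log link (via
#' [stats::glm.fit()]'s IRLS loop) and returns the pieces downstream
#' inference needs: coefficients, the inverse-information covariance
#' `(X'WX)^-1` (scaled by the Pearson dispersion for the quasi-Poisson
#' family), full log-likelihood, AIC including the `log(y!)` term, and the
#' Pearson dispersion statistic.
#'
#' @param y non-negative integer response.
#' @param X design matrix without an intercept column (one is prepended).
#' @param family `"poisson"` or `"quasipoisson"`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return an object of class `"dlnm_glm"`: list with `coefficients`
#'   (intercept first), `vcov`, `loglik`, `aic`, `dispersion`, `fitted`,
#'   `converged`, `n_used`, `family`, `y`.
#' @export
fit_poisson <- function(y, X, family = c("poisson", "quasipoisson"),
                        max_iter = 100L, tol = 1e-9) {
  family <- match.arg(family)
  stopifnot(length(y) == nrow(X), all(y >= 0))
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- glm.fit(Xi, y, family = poisson(),
                 control = list(epsilon = tol, maxit = max_iter))
  if (!fit$converged)
    stop("IRLS did not converge in ", max_iter, " iterations")
  p <- ncol(Xi)
  qr_ <- fit$qr
  if (qr_$rank < p) stop("design matrix is rank deficient")
  vcov <- chol2inv(qr_$qr[1:p, 1:p, drop = FALSE])
  dimnames(vcov) <- list(colnames(Xi), colnames(Xi))
  mu <- fit$fitted.values
  loglik <- sum(dpois(y, mu, log = TRUE))
  disp <- sum((y - mu)^2 / mu) / (length(y) - p)
  if (family == "quasipoisson") vcov <- vcov * disp
  structure(list(coefficients = setNames(fit$coefficients, colnames(Xi)),
                 vcov = vcov, loglik = loglik, aic = -2 * loglik + 2 * p,
                 dispersion = disp, fitted = mu, converged = fit$converged,
                 n_used = length(y), family = family, y = y),
            class = "dlnm_glm")
}

#' Pearson overdispersion statistic
#'
#' `sum((y - mu)^2 / mu)` over the rows entering the likelihood, divided by
#' the residual degrees of freedom. Values near 1 indicate equidispersed
#' (Poisson-like) counts; values well above 1 suggest refitting with
#' `family = "quasipoisson"`.
#'
#' @param fit a [fit_poisson()] or [dlnm_fit()] result.
#' @return the dispersion estimate.
#' @export
dispersion <- function(fit) {
  stopifnot(inherits(fit, c("dlnm_glm", "dlnm_fit")))
  fit$dispersion
}

#' Fit a distributed lag non-linear model to a daily series
#'
#' The central fitting function of the package. Models daily counts as
#' \deqn{Y_t \sim \mathrm{Poisson}(\mu_t), \quad
#'   \log \mu_t = \alpha + \beta^\top \mathrm{CB}_t(x) + \gamma^\top z_t
#'   + ns(t, df_{time}) + \eta^\top \mathrm{DOW}_t}
#' where `CB_t(x)` is the temperature cross-basis (natural cubic splines in
#' both the exposure and the lag dimension), `z_t` optional environmental
#' covariates (linear, except `rh` which enters as a natural spline smooth),
#' `ns(t, .)` a long-term/seasonality spline with `time_df_per_year` df per
#' year, and `DOW` day-of-week indicators. With no covariates this is the
#' single-factor model; with `covariates = c("tv", "rh", "pm25", "so2")`
#' the multi-factor model.
#'
#' The first `max_lag` rows of the series (incomplete lag history) are
#' excluded from the likelihood.
#'
#' @param series a [daily_series()] containing `temp_mean` and the outcome.
#' @param outcome count column to model (default `"stroke"`).
#' @param covariates character vector of covariate columns to adjust for;
#'   `"rh"` is entered as a natural spline smooth with `rh_df` df, all
#'   others linearly.
#' @param max_lag maximum lag in days (default 14).
#' @param exposure_df,lag_df cross-basis dimensions (defaults 6 and 4).
#' @param time_df_per_year seasonality df per year (default 12).
#' @param rh_df df of the relative-humidity smooth (default 3).
#' @param family `"poisson"` (default) or `"quasipoisson"`.
#' @param ref reference temperature for relative risks; default the median
#'   of the observed series.
#' @return an object of class `"dlnm_fit"`; see [predict.dlnm_fit()],
#'   [cumulative_rr()], [find_mmt()], [effect_tables()].
#' @examples
#' sim <- simulate_stroke_series(seed = 1, n_days = 400)
#' fit <- dlnm_fit(sim, covariates = c("tv", "rh", "pm25", "so2"))
#' fit
#' @export
dlnm_fit <- function(series, outcome = "stroke", covariates = character(),
                     max_lag = 14L, exposure_df = 6L, lag_df = 4L,
                     time_df_per_year = 12, rh_df = 3L,
                     family = c("poisson", "quasipoisson"), ref = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(series, "daily_series"))
  if (!"temp_mean" %in% names(series))
    stop("series must contain 'temp_mean'")
  cb <- crossbasis(series$temp_mean, max_lag = max_lag,
                   exposure_df = exposure_df, lag_df = lag_df)
  smooth <- list()
  linear <- covariates
  if ("rh" %in% covariates) {
    smooth$rh <- rh_df
    linear <- setdiff(covariates, "rh")
  }
  des <- build_design(series, cb, outcome = outcome, linear = linear,
                      smooth = smooth, time_df_per_year = time_df_per_year)
  glm_fit <- fit_poisson(des$y[des$mask], des$X[des$mask, , drop = FALSE],
                         family = family)
  cuts <- temp_cutpoints(series$temp_mean)
  if (is.null(ref)) ref <- unname(cuts["median"])

  fitted_full <- rep(NA_real_, nrow(series))
  fitted_full[des$mask] <- glm_fit$fitted

  structure(list(coefficients = glm_fit$coefficients, vcov = glm_fit$vcov,
                 loglik = glm_fit$loglik, aic = glm_fit$aic,
                 dispersion = glm_fit$dispersion,
                 fitted = fitted_full, converged = glm_fit$converged,
                 n_used = glm_fit$n_used, family = family,
                 crossbasis = cb, cutpoints = cuts, ref = ref,
                 term_index = des$term_index, mask = des$mask,
                 y = des$y, temp = series$temp_mean, outcome = outcome,
                 covariates = covariates, call = match.call()),
            class = "dlnm_fit")
}

#' Cross-basis model selection over a df grid
#'
#' Refits the model for every combination of exposure and lag df and ranks
#' by AIC; ties go to the smaller total df (then the smaller exposure df).
#' Individual fit failures are recorded in the table, not fatal.
#'
#' @inheritParams dlnm_fit
#' @param exposure_df_grid,lag_df_grid integer vectors of candidate df.
#' @param ... further arguments passed to [dlnm_fit()].
#' @return list with `exposure_df`, `lag_df` (the AIC-minimal pair), `fit`
#'   (the refit at that pair) and `table`
#'   (`exposure_df`, `lag_df`, `aic`, `converged`).
#' @export
select_df <- function(series, exposure_df_grid, lag_df_grid, ...) {
  stopifnot(length(exposure_df_grid) >= 1L, length(lag_df_grid) >= 1L)
  grid <- expand.grid(exposure_df = as.integer(exposure_df_grid),
                      lag_df = as.integer(lag_df_grid))
  fits <- vector("list", nrow(grid))
  aic <- rep(NA_real_, nrow(grid))
  conv <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(dlnm_fit(series, exposure_df = grid$exposure_df[i],
                           lag_df = grid$lag_df[i], ...),
                  error = function(e) NULL)
    if (!is.null(f)) {
      fits[[i]] <- f
      aic[i] <- f$aic
      conv[i] <- f$converged
    }
  }
  tab <- cbind(grid, aic = aic, converged = conv)
  ok <- which(conv & !is.na(aic))
  if (!length(ok)) stop("all fits in the df grid failed")
  o <- ok[order(aic[ok], grid$exposure_df[ok] + grid$lag_df[ok],
                grid$exposure_df[ok])]
  best <- o[1L]
  list(exposure_df = grid$exposure_df[best], lag_df = grid$lag_df[best],
       fit = fits[[best]], table = tab)
}

#' @export
print.dlnm_fit <- function(x, digits = 4L, ...) {
  cat("Distributed lag non-linear model (", x$family, ")\n", sep = "")
  cat("  outcome: ", x$outcome,
      if (length(x$covariates))
        paste0("; covariates: ", paste(x$covariates, collapse = ", ")),
      "\n", sep = "")
  cat("  cross-basis: exposure df ", x$crossbasis$exposure_spec$df,
      " x lag df ",
      if (is.null(x$crossbasis$lag_spec)) 1L else x$crossbasis$lag_spec$df,
      ", max lag ", x$crossbasis$max_lag, "\n", sep = "")
  cat("  n used: ", x$n_used, "; AIC: ", format(x$aic, digits = digits + 2L),
      "; dispersion: ", format(x$dispersion, digits = digits),
      "\n", sep = "")
  cat("  reference temperature: ", format(x$ref, digits = digits),
      " degC\n", sep = "")
  invisible(x)
}

#' @export
coef.dlnm_fit <- function(object, ...) object$coefficients

#' @export
vcov.dlnm_fit <- function(object, ...) object$vcov

#' @export
logLik.dlnm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_used, class = "logLik")
}

#' @export
fitted.dlnm_fit <- function(object, ...) object$fitted

#' @export
residuals.dlnm_fit <- function(object,
                               type = c("pearson", "deviance", "response"),
                               ...) {
  type <- match.arg(type)
  y <- object$y[object$mask]
  mu <- object$fitted[object$mask]
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = {
           d <- 2 * (dpois(y, y, log = TRUE) - dpois(y, mu, log = TRUE))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' Simulate counts from a fitted model
#'
#' Draws Poisson counts at the fitted means (days excluded from the
#' likelihood give `NA`), useful for parametric-bootstrap checks.
#'
#' @param object a [dlnm_fit()].
#' @param nsim number of replicate series.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a `data.frame` with `nsim` columns of simulated counts.
#' @export
simulate.dlnm_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    y <- rep(NA_integer_, length(mu))
    y[!is.na(mu)] <- rpois(sum(!is.na(mu)), mu[!is.na(mu)])
    y
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
summary.dlnm_fit <- function(object, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  keep <- unlist(object$term_index[setdiff(names(object$term_index),
                                           c("crossbasis", "time_ns"))],
                 use.names = FALSE)
  keep <- c(1L, keep)
  est <- object$coefficients[keep]
  se <- sqrt(diag(object$vcov)[keep])
  tab <- data.frame(estimate = est, se = se, z = est / se,
                    p = 2 * pnorm(-abs(est / se)),
                    lo = est - z * se, hi = est + z * se)
  out <- list(fit = object, coef_table = tab, level = level)
  class(out) <- "summary.dlnm_fit"
  out
}

#' @export
print.summary.dlnm_fit <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  cat("\nIntercept and covariate coefficients (",
      round(100 * x$level), "% CI):\n", sep = "")
  print(round(x$coef_table, digits))
  invisible(x)
}
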