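#' Analysis configuration
#'
#' Default settings of the two-stage analysis: cross-basis dimensions
#' (exposure df 6, lag df 4, max lag 14), seasonality df (12 per year),
#' relative-humidity smooth df (3), percentile cutpoints
#' (1/10/50/90/99), cumulative lag windows (0-3, 0-7, 0-10, 0-14),
#' Spearman screening threshold (0.6), sensitivity df grids (exposure 4-8,
#' lag 2-6), the multi-factor covariate set and the subgroup list. Any
#' entry can be overridden via `...`.
#'
#' @param ... named overrides.
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    max_lag = 14L, exposure_df = 6L, lag_df = 4L,
    time_df_per_year = 12, rh_df = 3L,
    cutpoint_probs = c(0.01, 0.10, 0.50, 0.90, 0.99),
    windows = list(c(0, 3), c(0, 7), c(0, 10), c(0, 14)),
    screening_threshold = 0.6,
    sens_exposure_df = 4:8, sens_lag_df = 2:6,
    covariates = c("tv", "rh", "pm25", "so2"),
    subgroups = c("is", "hs", "age_lt65", "age_ge65", "male", "female"),
    family = "poisson",
    ref_value = NULL           # NULL: median reference; numeric: fixed degC
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "analysis_config")
}

#' Spearman collinearity screening
#'
#' Rank correlations (average ranks for ties) among candidate covariates,
#' with greedy exclusion of collinear members: while any pair exceeds the
#' threshold in absolute value, drop — among the members of offending
#' pairs that are not protected — the variable with the largest mean
#' absolute correlation to the remaining candidates (ties broken
#' alphabetically). The exposure of interest is protected and never
#' dropped.
#'
#' @param series a [daily_series()].
#' @param candidates covariate columns to screen; default every recognised
#'   covariate present in `series`.
#' @param threshold exclusion threshold on `|rho|` (default 0.6, strict).
#' @param protected columns never dropped (default `"temp_mean"`).
#' @return list with `kept`, `dropped`, `constant` (flagged undefined
#'   columns), `correlation` (the full Spearman matrix), and
#'   `dropped_pairs` (`var1`, `var2`, `rho` for every offending pair).
#' @export
spearman_screen <- function(series, candidates = NULL, threshold = 0.6,
                            protected = "temp_mean") {
  if (is.null(candidates))
    candidates <- intersect(covariate_columns(), names(series))
  stopifnot(length(candidates) >= 2L,
            all(candidates %in% names(series)))
  mat <- as.matrix(as.data.frame(series)[candidates])
  constant <- candidates[apply(mat, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2L || length(unique(v)) == 1L
  })]
  if (length(constant))
    warning("constant column(s) excluded from screening: ",
            paste(constant, collapse = ", "))
  vars <- setdiff(candidates, constant)
  R <- cor(mat[, vars, drop = FALSE], method = "spearman",
           use = "pairwise.complete.obs")

  offending <- function(v) {
    r <- abs(R[v, v, drop = FALSE])
    diag(r) <- 0
    which(r > threshold, arr.ind = TRUE)
  }
  pairs0 <- offending(vars)
  dropped_pairs <- if (nrow(pairs0)) {
    keep <- pairs0[, 1L] < pairs0[, 2L]
    v <- vars
    data.frame(var1 = v[pairs0[keep, 1L]], var2 = v[pairs0[keep, 2L]],
               rho = R[pairs0[keep, , drop = FALSE]])
  } else {
    data.frame(var1 = character(), var2 = character(), rho = numeric())
  }

  kept <- vars
  dropped <- character()
  repeat {
    off <- offending(kept)
    if (!nrow(off)) break
    members <- setdiff(unique(kept[off[, 1L]]), protected)
    if (!length(members)) break
    score <- vapply(members, function(m) {
      mean(abs(R[m, setdiff(kept, m)]))
    }, numeric(1L))
    drop <- sort(members[score == max(score)])[1L]
    dropped <- c(dropped, drop)
    kept <- setdiff(kept, drop)
  }
  list(kept = kept, dropped = dropped, constant = constant,
       correlation = R, dropped_pairs = dropped_pairs)
}

#' Exploratory single-factor exposure-response curve
#'
#' Poisson regression of the counts on a natural cubic spline smooth
#' (df 3 by default) of one environmental factor, adjusted for the
#' long-term/seasonal spline and day-of-week, alongside a linear
#' competitor. The curve is centered at the factor's mean (log-rate 0
#' there); the AIC comparison classifies the relationship as
#' approximately linear or non-linear.
#'
#' @param series a [daily_series()].
#' @param factor name of the environmental column to explore.
#' @param outcome count column (default `"stroke"`).
#' @param df smooth df (default 3).
#' @param time_df_per_year seasonality df per year.
#' @param grid_length number of curve evaluation points.
#' @param level confidence level for the pointwise band.
#' @return list with `factor`, `curve` (`x`, `log_rate`, `se`, `rr`, `lo`,
#'   `hi`), `aic_smooth`, `aic_linear`, `classification`.
#' @export
explore_gam <- function(series, factor, outcome = "stroke", df = 3L,
                        time_df_per_year = 12, grid_length = 50L,
                        level = 0.95) {
  stopifnot(inherits(series, "daily_series"), factor %in% names(series))
  x <- series[[factor]]
  y <- series[[outcome]]
  tb <- natural_spline_basis(series$t, basis_spec(
    max(2L, as.integer(round(time_df_per_year * nrow(series) / 365.25)))))
  dow <- dow_dummies(series$date)

  fb <- natural_spline_basis(x, basis_spec(df))
  colnames(fb) <- paste0("f", seq_len(df))
  mask <- !is.na(y) & !is.na(x)
  Xs <- cbind(fb, tb, dow)
  Xl <- cbind(f1 = x, tb, dow)
  fit_s <- fit_poisson(y[mask], Xs[mask, , drop = FALSE])
  fit_l <- fit_poisson(y[mask], Xl[mask, , drop = FALSE])

  z <- qnorm(1 - (1 - level) / 2)
  spec <- attr(fb, "spec")
  grid <- seq(min(x, na.rm = TRUE), max(x, na.rm = TRUE),
              length.out = grid_length)
  Cg <- eval_basis(spec, grid) -
    matrix(eval_basis(spec, mean(x, na.rm = TRUE)), grid_length, df,
           byrow = TRUE)
  idx <- 1L + seq_len(df)
  beta <- fit_s$coefficients[idx]
  V <- fit_s$vcov[idx, idx, drop = FALSE]
  lr <- as.vector(Cg %*% beta)
  se <- sqrt(pmax(rowSums((Cg %*% V) * Cg), 0))
  curve <- data.frame(x = grid, log_rate = lr, se = se, rr = exp(lr),
                      lo = exp(lr - z * se), hi = exp(lr + z * se))
  list(factor = factor, curve = curve, aic_smooth = fit_s$aic,
       aic_linear = fit_l$aic,
       classification = if (fit_l$aic <= fit_s$aic) "linear"
                        else "nonlinear")
}

## shared fit + report core of the run_* wrappers
fit_and_report <- function(series, config, outcome, covariates) {
  fit <- dlnm_fit(series, outcome = outcome, covariates = covariates,
                  max_lag = config$max_lag,
                  exposure_df = config$exposure_df,
                  lag_df = config$lag_df,
                  time_df_per_year = config$time_df_per_year,
                  rh_df = config$rh_df, family = config$family,
                  ref = config$ref_value)
  cuts <- temp_cutpoints(series$temp_mean, config$cutpoint_probs)
  tables <- effect_tables(fit, cutpoints = cuts, windows = config$windows)
  list(fit = fit, cutpoints = cuts, tables = tables, aic = fit$aic)
}

#' Single-factor DLNM analysis
#'
#' Fits the temperature-only model (cross-basis + seasonality + day of
#' week), and reports the percentile cutpoints, the lag-specific and
#' cumulative relative-risk tables, the predicted effect surface and the
#' minimum-morbidity temperature.
#'
#' @param series a [daily_series()].
#' @param config an [analysis_config()].
#' @return list with `fit`, `cutpoints`, `tables`, `surface`, `mmt`,
#'   `aic`.
#' @export
run_single_factor <- function(series, config = analysis_config()) {
  out <- fit_and_report(series, config, "stroke", character())
  out$surface <- predict(out$fit, windows = config$windows)
  out$mmt <- find_mmt(out$fit)
  out
}

#' Multi-factor DLNM analysis
#'
#' As [run_single_factor()] but adjusting for the screened covariate set
#' (by default TV linear, relative humidity as a df-3 smooth, PM2.5 and
#' SO2 linear), and additionally reporting the covariate coefficients with
#' confidence intervals.
#'
#' @inheritParams run_single_factor
#' @param covariates covariate set; default `config$covariates`.
#' @return list with `fit`, `cutpoints`, `tables`, `surface`, `mmt`,
#'   `aic`, `covariate_coef`.
#' @export
run_multi_factor <- function(series, config = analysis_config(),
                             covariates = config$covariates) {
  out <- fit_and_report(series, config, "stroke", covariates)
  out$surface <- predict(out$fit, windows = config$windows)
  out$mmt <- find_mmt(out$fit)
  out$covariate_coef <- summary(out$fit)$coef_table
  out
}

#' Subgroup DLNM analyses
#'
#' Refits the multi-factor model for each subgroup outcome (stroke type,
#' age group, sex) and assembles the cumulative relative-risk table per
#' group. All groups share the full-series percentile cutpoints and the
#' base cross-basis dimensions.
#'
#' @inheritParams run_multi_factor
#' @return list with `groups` (per-group `fit` and `tables`) and
#'   `cumulative`, one `data.frame` of group x temperature x window rows.
#' @export
run_subgroups <- function(series, config = analysis_config(),
                          covariates = config$covariates) {
  groups <- intersect(config$subgroups, names(series))
  if (!length(groups)) stop("no subgroup count columns present")
  res <- lapply(groups, function(g) {
    if (mean(series[[g]], na.rm = TRUE) < 1)
      warning("subgroup '", g, "' has mean daily count < 1")
    out <- fit_and_report(series, config, g, covariates)
    out$tables$cumulative$group <- g
    out
  })
  names(res) <- groups
  cumulative <- do.call(rbind, lapply(res, function(r) r$tables$cumulative))
  rownames(cumulative) <- NULL
  list(groups = res, cumulative = cumulative)
}

#' Sensitivity analyses
#'
#' Two robustness checks of the multi-factor model: (a) re-centering the
#' relative risks at the minimum-morbidity temperature instead of the
#' median; (b) refitting over the exposure df 4-8 x lag df 2-6 grid and
#' reporting the cumulative (0..max lag) cold and hot relative risks per
#' cell, flagging cells deviating more than 25\% from the base
#' specification. Individual cell failures are recorded and the run
#' continues.
#'
#' @inheritParams run_multi_factor
#' @param base optional result of [run_multi_factor()] to reuse.
#' @return list with `mmt`, `recentered` (effect tables referenced at the
#'   MMT), and `grid` (`exposure_df`, `lag_df`, `rr_cold`, `rr_hot`,
#'   `converged`, `flag_cold`, `flag_hot`).
#' @export
run_sensitivity <- function(series, config = analysis_config(),
                            covariates = config$covariates, base = NULL) {
  if (is.null(base)) base <- run_multi_factor(series, config, covariates)
  mmt <- base$mmt
  recentered <- effect_tables(base$fit, cutpoints = base$cutpoints,
                              windows = config$windows, ref = mmt)
  cold <- unname(base$cutpoints["p1"])
  hot <- unname(base$cutpoints["p99"])
  W <- c(0, config$max_lag)
  base_cold <- cumulative_rr(base$fit, cold, window = W)$rr
  base_hot <- cumulative_rr(base$fit, hot, window = W)$rr

  grid <- expand.grid(exposure_df = config$sens_exposure_df,
                      lag_df = config$sens_lag_df)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- config
    cfg_i$exposure_df <- grid$exposure_df[i]
    cfg_i$lag_df <- grid$lag_df[i]
    f <- tryCatch(fit_and_report(series, cfg_i, "stroke", covariates),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(exposure_df = grid$exposure_df[i],
                        lag_df = grid$lag_df[i], rr_cold = NA_real_,
                        rr_hot = NA_real_, converged = FALSE))
    data.frame(exposure_df = grid$exposure_df[i], lag_df = grid$lag_df[i],
               rr_cold = cumulative_rr(f$fit, cold, window = W)$rr,
               rr_hot = cumulative_rr(f$fit, hot, window = W)$rr,
               converged = TRUE)
  })
  tab <- do.call(rbind, rows)
  tab$flag_cold <- abs(tab$rr_cold - base_cold) / base_cold > 0.25
  tab$flag_hot <- abs(tab$rr_hot - base_hot) / base_hot > 0.25
  list(mmt = mmt, recentered = recentered, grid = tab,
       base_cold = base_cold, base_hot = base_hot)
}

#' Run the complete two-stage analysis
#'
#' Screening, single-factor and multi-factor DLNM, subgroups and
#' sensitivity analyses in one call, optionally writing the result tables
#' as CSV files.
#'
#' @inheritParams run_single_factor
#' @param out_dir optional directory; when given, the correlation matrix,
#'   the effect tables and the sensitivity grid are written there as CSV.
#' @return list with `screening`, `single`, `multi`, `subgroups`,
#'   `sensitivity`.
#' @export
run_all <- function(series, config = analysis_config(), out_dir = NULL) {
  screening <- spearman_screen(series,
                               threshold = config$screening_threshold)
  single <- run_single_factor(series, config)
  multi <- run_multi_factor(series, config)
  subgroups <- if (any(config$subgroups %in% names(series)))
    run_subgroups(series, config) else NULL
  sensitivity <- run_sensitivity(series, config, base = multi)
  out <- list(screening = screening, single = single, multi = multi,
              subgroups = subgroups, sensitivity = sensitivity)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) write.csv(x, file.path(out_dir, f),
                                   row.names = FALSE)
    write.csv(round(screening$correlation, 4L),
              file.path(out_dir, "spearman_correlation.csv"))
    wr(single$tables$cumulative, "single_cumulative.csv")
    wr(single$tables$lag_specific, "single_lag_specific.csv")
    wr(multi$tables$cumulative, "multi_cumulative.csv")
    wr(multi$tables$lag_specific, "multi_lag_specific.csv")
    if (!is.null(subgroups)) wr(subgroups$cumulative,
                                "subgroup_cumulative.csv")
    wr(sensitivity$grid, "sensitivity_grid.csv")
  }
  out
}
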