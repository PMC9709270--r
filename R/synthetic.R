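#' Planted exposure-lag-response surface
#'
#' The ground-truth log relative-risk surface used by the synthetic
#' generator, built from two separable regime components hinged at the
#' minimum-morbidity temperature `mmt`:
#' \itemize{
#'   \item cold: `g_cold(x) * w_cold(l)` with
#'     `g_cold(x) = max(0, (mmt - x) / (mmt - cold_anchor))` and
#'     `w_cold(l) = log(cold_rr) * (l / max_lag)^p` — risk rising with lag
#'     up to the last lag day;
#'   \item hot: `g_hot(x) * w_hot(l)` with
#'     `g_hot(x) = max(0, (x - mmt) / (hot_anchor - mmt))` and a triangular
#'     lag weight `log(hot_rr) * max(0, 1 - |l - hot_peak_lag| /
#'     (hot_zero_lag - hot_peak_lag))`, vanishing beyond `hot_zero_lag` —
#'     an acute effect peaking mid-window.
#' }
#' The exponent `p` is solved numerically at construction so that the
#' cumulative cold effect `sum_l w_cold(l)` equals `log(cold_cum_rr)`. The
#' surface is exactly zero at `x = mmt` for every lag.
#'
#' Default anchors: single-lag cold RR 1.20 at (`cold_anchor` = -10 degC,
#' lag 14), cumulative cold RR 2.02 over lags 0-14, hot RR 1.07 at
#' (`hot_anchor` = 30 degC, lag 6).
#'
#' @param mmt hinge (minimum-risk) temperature, deg C.
#' @param cold_rr relative risk at (`cold_anchor`, `max_lag`).
#' @param cold_cum_rr cumulative (0..`max_lag`) relative risk at
#'   `cold_anchor`; set both cold values to 1 for a null cold component.
#' @param cold_anchor,hot_anchor anchor temperatures, deg C.
#' @param hot_rr relative risk at (`hot_anchor`, `hot_peak_lag`).
#' @param hot_peak_lag,hot_zero_lag peak and extinction lags of the hot
#'   component.
#' @param max_lag lag-window length (days).
#' @return an object of class `"true_surface"`.
#' @export
true_surface <- function(mmt = 17, cold_rr = 1.20, cold_cum_rr = 2.02,
                         cold_anchor = -10, hot_rr = 1.07,
                         hot_anchor = 30, hot_peak_lag = 6L,
                         hot_zero_lag = 10L, max_lag = 14L) {
  stopifnot(cold_anchor < mmt, mmt < hot_anchor,
            hot_peak_lag < hot_zero_lag, hot_zero_lag <= max_lag,
            cold_rr > 0, cold_cum_rr > 0, hot_rr > 0)
  cold_scale <- log(cold_rr)
  if (cold_scale == 0) {
    p <- 1
    if (log(cold_cum_rr) != 0)
      stop("null single-lag cold effect with non-null cumulative target")
  } else {
    ratio <- log(cold_cum_rr) / cold_scale
    l <- 0:max_lag
    if (ratio <= 1 || ratio >= max_lag)
      stop("infeasible calibration: cumulative/single-lag log-RR ratio ",
           signif(ratio, 4L), " outside (1, ", max_lag, ")")
    p <- uniroot(function(p) sum((l / max_lag)^p) - ratio,
                 interval = c(1e-6, 60), tol = 1e-12)$root
  }
  structure(list(mmt = mmt, cold_scale = cold_scale,
                 cold_anchor = cold_anchor, cold_lag_power = p,
                 hot_scale = log(hot_rr), hot_anchor = hot_anchor,
                 hot_peak_lag = as.integer(hot_peak_lag),
                 hot_zero_lag = as.integer(hot_zero_lag),
                 max_lag = as.integer(max_lag)),
            class = "true_surface")
}

## regime components, vectorized over x (temperatures) and l (lags)
surface_g_cold <- function(s, x) {
  pmax(0, (s$mmt - x) / (s$mmt - s$cold_anchor))
}
surface_w_cold <- function(s, l) {
  s$cold_scale * (l / s$max_lag)^s$cold_lag_power
}
surface_g_hot <- function(s, x) {
  pmax(0, (x - s$mmt) / (s$hot_anchor - s$mmt))
}
surface_w_hot <- function(s, l) {
  s$hot_scale * pmax(0, 1 - abs(l - s$hot_peak_lag) /
                          (s$hot_zero_lag - s$hot_peak_lag)) *
    (l <= s$hot_zero_lag)
}

#' Evaluate the planted surface
#'
#' True log relative risk (versus the hinge temperature `mmt`) of
#' temperature `x` at lag `l`.
#'
#' @param surface a [true_surface()].
#' @param x temperature(s), deg C.
#' @param l lag(s) in `0..max_lag`; recycled against `x`.
#' @return numeric vector of log relative risks.
#' @export
true_log_rr <- function(surface, x, l) {
  stopifnot(inherits(surface, "true_surface"))
  if (any(l < 0 | l > surface$max_lag))
    stop("lag outside [0, ", surface$max_lag, "]")
  surface_g_cold(surface, x) * surface_w_cold(surface, l) +
    surface_g_hot(surface, x) * surface_w_hot(surface, l)
}

#' @export
print.true_surface <- function(x, ...) {
  cat("Planted exposure-lag surface (hinge at ", x$mmt, " degC)\n",
      "  cold: log-RR ", signif(x$cold_scale, 4L), " at ", x$cold_anchor,
      " degC, lag ", x$max_lag, "; lag power ",
      signif(x$cold_lag_power, 4L), "\n",
      "  hot:  log-RR ", signif(x$hot_scale, 4L), " at ", x$hot_anchor,
      " degC, peak lag ", x$hot_peak_lag, ", zero beyond lag ",
      x$hot_zero_lag, "\n", sep = "")
  invisible(x)
}

#' Default generator configuration
#'
#' All tunables of the synthetic Beijing-like scenario: series length,
#' marginal/seasonal/autocorrelation parameters of each environmental
#' variable (calibrated to the published two-year summary statistics),
#' outcome baseline and covariate effect sizes, day-of-week effects, trend,
#' and subgroup split probabilities. Override any entry via `...`.
#'
#' Covariate effect sizes (`gamma_tv`, `rh_quad`/`rh_center`,
#' `delta_pm25`, `zeta_so2`) are conventions, not published values: small
#' positive TV and PM2.5 effects, a negative SO2 effect and a U-shaped
#' relative-humidity term, matching the directions reported for this kind
#' of data.
#'
#' @param ... named overrides of any default entry.
#' @return a named list of class `"generator_config"`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_days = 730L,
    start_date = as.Date("2017-01-01"),
    burn_in = 14L,
    ## temperature: mean + annual sinusoid + second harmonic + AR(1)
    temp_mean = 12.07, temp_amplitude = 16, temp_harmonic2 = 1.8,
    temp_phase_day = 15, temp_ar_rho = 0.7, temp_ar_sd = 3.0,
    ## diurnal temperature variation
    tv_mean = 11.87, tv_amplitude = 1.5, tv_phase_day = 105, tv_sd = 3.8,
    tv_range = c(2.2, 23.8),
    ## relative humidity (summer-peaked)
    rh_mean = 52.76, rh_amplitude = 16, rh_ar_rho = 0.6, rh_sd = 14,
    rh_range = c(14, 95),
    ## pressure and ozone couple to temperature; wind to humidity
    pressure_mean = 993.76, pressure_temp_slope = -0.55, pressure_sd = 4,
    o3_mean = 61.6, o3_temp_slope = 2.3, o3_sd = 20,
    wind_mean = 1.70, wind_rh_slope = -0.022, wind_sd = 0.25,
    wind_range = c(0.4, 5.1),
    ## pollutants: log-normal with winter elevation; PM10 and CO derived
    pm25_meanlog = 3.60, pm25_winter = 0.45, pm25_sdlog = 0.75,
    pm25_ar_rho = 0.5, pm25_temp_coupling = -0.10,
    pm10_factor = 1.40, pm10_noise_sd = 12,
    so2_meanlog = 1.35, so2_winter = 0.55, so2_sdlog = 0.75,
    so2_ar_rho = 0.5,
    no2_meanlog = 3.58, no2_winter = 0.15, no2_sdlog = 0.45,
    co_factor = 0.105, co_base = 0.25, co_noise_sd = 0.08,
    ## precipitation: summer-weighted wet days, exponential amounts
    precip_p_dry = 0.06, precip_p_summer = 0.28, precip_mean_amount = 11,
    ## outcome model
    mean_count = 36.96,
    gamma_tv = 0.004, rh_center = 70, rh_quad = 2.5e-5,
    delta_pm25 = 1e-3, zeta_so2 = -0.003,
    trend = -0.03,
    dow_effects = c(Mon = 0.02, Tue = 0.00, Wed = 0.00, Thu = -0.01,
                    Fri = 0.01, Sat = -0.01, Sun = -0.02),
    ## subgroup thinning: baseline shares and cold-signal modulation
    split_is = 17388 / 26984, split_age_ge65 = 24.00 / 36.96,
    split_male = 21.92 / 36.96,
    split_modulation = c(is = 0.30, age_ge65 = 0.20, male = 0.20)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "generator_config")
}

#' Read a scenario configuration file
#'
#' Loads a YAML key/value file of [generator_config()] overrides and merges
#' it over the defaults. Keys must match configuration entry names.
#'
#' @param path path to a YAML file.
#' @return a `"generator_config"`.
#' @examples
#' if (requireNamespace("yaml", quietly = TRUE)) {
#'   p <- system.file("extdata", "scenario-null-surface.yml",
#'                    package = "templag")
#'   read_scenario_config(p)$gamma_tv
#' }
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read scenario files")
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$start_date)) vals$start_date <- as.Date(vals$start_date)
  do.call(generator_config, vals)
}

## marginal-sd AR(1) path; caller controls the RNG state
ar1_path <- function(n, rho, sd_marginal) {
  e <- numeric(n)
  e[1L] <- rnorm(1L, 0, sd_marginal)
  inn <- rnorm(n, 0, sd_marginal * sqrt(1 - rho^2))
  for (i in seq_len(n)[-1L]) e[i] <- rho * e[i - 1L] + inn[i]
  e
}

## environment simulation core; tt may extend before day 1 (burn-in)
sim_environment_frame <- function(config, tt) {
  n <- length(tt)
  theta <- 2 * pi * (tt - config$temp_phase_day) / 365.25
  winter <- cos(theta)                      # 1 mid-January, -1 mid-July
  temp_resid <- ar1_path(n, config$temp_ar_rho, config$temp_ar_sd)
  temp <- config$temp_mean -
    config$temp_amplitude * winter -
    config$temp_harmonic2 * cos(2 * theta) +
    temp_resid

  theta_tv <- 2 * pi * (tt - config$tv_phase_day) / 365.25
  tv <- config$tv_mean + config$tv_amplitude * cos(theta_tv) +
    rnorm(n, 0, config$tv_sd)
  tv <- pmin(pmax(tv, config$tv_range[1L]), config$tv_range[2L])

  rh <- config$rh_mean - config$rh_amplitude * winter +
    ar1_path(n, config$rh_ar_rho, config$rh_sd)
  rh <- pmin(pmax(rh, config$rh_range[1L]), config$rh_range[2L])

  pressure <- config$pressure_mean +
    config$pressure_temp_slope * (temp - config$temp_mean) +
    rnorm(n, 0, config$pressure_sd)
  o3 <- pmax(config$o3_mean + config$o3_temp_slope *
               (temp - config$temp_mean) + rnorm(n, 0, config$o3_sd), 1)
  wind <- config$wind_mean +
    config$wind_rh_slope * (rh - config$rh_mean) +
    rnorm(n, 0, config$wind_sd)
  wind <- pmin(pmax(wind, config$wind_range[1L]), config$wind_range[2L])

  ## cold anomalies co-occur with stagnant, high-PM episodes: log-PM2.5
  ## couples negatively to the day-to-day temperature residual, giving the
  ## short-term confounding that makes single- vs multi-factor estimates
  ## genuinely differ
  pm25 <- exp(config$pm25_meanlog + config$pm25_winter * winter +
                config$pm25_temp_coupling * temp_resid +
                ar1_path(n, config$pm25_ar_rho, config$pm25_sdlog))
  pm10 <- pm25 * config$pm10_factor + abs(rnorm(n, 0, config$pm10_noise_sd))
  so2 <- exp(config$so2_meanlog + config$so2_winter * winter +
               ar1_path(n, config$so2_ar_rho, config$so2_sdlog))
  no2 <- exp(config$no2_meanlog + config$no2_winter * winter +
               rnorm(n, 0, config$no2_sdlog))
  co <- pmax(config$co_base + config$co_factor * so2 +
               rnorm(n, 0, config$co_noise_sd), 0.1)

  p_wet <- config$precip_p_dry + config$precip_p_summer * pmax(0, -winter)
  wet <- runif(n) < p_wet
  precip <- ifelse(wet, -config$precip_mean_amount * log(runif(n)), 0)

  data.frame(date = config$start_date + (tt - 1L),
             temp_mean = temp, tv = tv, rh = rh, pressure = pressure,
             precip = precip, wind = wind, no2 = no2, so2 = so2, o3 = o3,
             pm25 = pm25, pm10 = pm10, co = co)
}

#' Generate a synthetic daily environment series
#'
#' Beijing-like daily weather and pollution: temperature as an annual
#' sinusoid (with a second harmonic skewing the marginal towards a long
#' cold tail) plus AR(1) noise; humidity and diurnal range seasonal with
#' noise; pressure, ozone and wind coupled to temperature or humidity; and
#' log-normal winter-elevated pollutants with PM10 and CO derived from
#' PM2.5 and SO2 so their rank correlations exceed the 0.6 screening
#' threshold. PM2.5 additionally couples (negatively) to the day-to-day
#' temperature residual, mimicking cold-snap/stagnation dynamics. Fully
#' reproducible given `seed`.
#'
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @param n_days series length; default `config$n_days`.
#' @return a [daily_series()] with environment columns and no counts.
#' @export
generate_environment <- function(config = generator_config(), seed = 1L,
                                 n_days = config$n_days) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  daily_series(sim_environment_frame(config, seq_len(n_days)))
}

## cold-regime cumulative signal per day, for subgroup modulation
cold_signal <- function(surface, temp_ext, n, burn_in) {
  w <- surface_w_cold(surface, 0:surface$max_lag)
  g <- surface_g_cold(surface, temp_ext)
  s <- numeric(n)
  for (l in 0:surface$max_lag)
    s <- s + g[(burn_in + 1L):(burn_in + n) - l] * w[l + 1L]
  s
}

#' Fill outcome counts from the planted surface
#'
#' Computes the daily Poisson rate
#' `lambda_t = exp(base + sum_l f(x_(t-l), l) + gamma_TV TV_t + s(RH_t) +
#' delta PM25_t + zeta SO2_t + trend_t + dow_t)` with `f` the planted
#' [true_surface()], draws `Y_t ~ Poisson(lambda_t)`, and thins the totals
#' into subgroup counts (IS/HS, age, sex) with binomial splits whose
#' probabilities are modulated by the cold-regime signal so that planted
#' subgroup contrasts are recoverable. The intercept `base` is calibrated
#' so the expected daily count equals `config$mean_count`.
#'
#' The first `max_lag` days of `env` get their lag history from a 14-day
#' burn-in extension of the temperature process (seasonal part plus a
#' time-reversed continuation of the AR noise), so every returned day has
#' a complete exposure history.
#'
#' @param env a [daily_series()] of environment columns (e.g. from
#'   [generate_environment()]).
#' @param surface a [true_surface()].
#' @param config a [generator_config()].
#' @param seed integer RNG seed.
#' @return `env` with count columns `stroke`, `is`, `hs`, `age_lt65`,
#'   `age_ge65`, `male`, `female` filled in.
#' @export
generate_counts <- function(env, surface = true_surface(),
                            config = generator_config(), seed = 1L) {
  stopifnot(inherits(env, "daily_series"), inherits(surface, "true_surface"),
            inherits(config, "generator_config"))
  n <- nrow(env)
  burn <- max(config$burn_in, surface$max_lag)
  set.seed(seed + 123456L)

  ## burn-in: seasonal temperature before day 1 plus a time-reversed AR
  ## continuation anchored at the first observed residual
  tt0 <- (1L - burn):0L
  theta0 <- 2 * pi * (tt0 - config$temp_phase_day) / 365.25
  seasonal0 <- config$temp_mean -
    config$temp_amplitude * cos(theta0) -
    config$temp_harmonic2 * cos(2 * theta0)
  theta1 <- 2 * pi * (1L - config$temp_phase_day) / 365.25
  seasonal1 <- config$temp_mean - config$temp_amplitude * cos(theta1) -
    config$temp_harmonic2 * cos(2 * theta1)
  e <- env$temp_mean[1L] - seasonal1
  rho <- config$temp_ar_rho
  inn <- rnorm(burn, 0, config$temp_ar_sd * sqrt(1 - rho^2))
  e_back <- numeric(burn)
  for (i in burn:1L) {               # e_back[burn] is the day before day 1
    e <- rho * e + inn[i]
    e_back[burn - i + 1L] <- e
  }
  temp_ext <- c(seasonal0 + rev(e_back), env$temp_mean)

  ## planted exposure-lag contribution, full surface
  w_cold <- surface_w_cold(surface, 0:surface$max_lag)
  w_hot <- surface_w_hot(surface, 0:surface$max_lag)
  g_cold <- surface_g_cold(surface, temp_ext)
  g_hot <- surface_g_hot(surface, temp_ext)
  planted <- numeric(n)
  idx <- (burn + 1L):(burn + n)
  for (l in 0:surface$max_lag)
    planted <- planted + g_cold[idx - l] * w_cold[l + 1L] +
      g_hot[idx - l] * w_hot[l + 1L]

  dow <- config$dow_effects[c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri",
                              "Sat")[as.POSIXlt(env$date)$wday + 1L]]
  eta <- planted +
    config$gamma_tv * (env$tv - config$tv_mean) +
    config$rh_quad * ((env$rh - config$rh_center)^2 -
                        (config$rh_mean - config$rh_center)^2) +
    config$delta_pm25 * (env$pm25 - exp(config$pm25_meanlog)) +
    config$zeta_so2 * (env$so2 - exp(config$so2_meanlog)) +
    config$trend * (env$t / max(env$t) - 0.5) +
    unname(dow)
  base <- log(config$mean_count) - log(mean(exp(eta)))
  lambda <- exp(base + eta)
  if (any(!is.finite(lambda)) || any(lambda > 1e7))
    stop("rate overflow on ", format(env$date[which.max(lambda)]))

  y <- rpois(n, lambda)

  ## subgroup thinning, cold-signal modulated on the logit scale
  cold <- cold_signal(surface, temp_ext, n, burn)
  cold_c <- cold - mean(cold)
  mod <- config$split_modulation
  thin <- function(p0, kappa) {
    p <- stats::plogis(stats::qlogis(p0) + kappa * cold_c)
    rbinom(n, y, p)
  }
  is_ <- thin(config$split_is, mod[["is"]])
  ge65 <- thin(config$split_age_ge65, mod[["age_ge65"]])
  male <- thin(config$split_male, mod[["male"]])

  env$stroke <- y
  env$is <- is_
  env$hs <- y - is_
  env$age_ge65 <- ge65
  env$age_lt65 <- y - ge65
  env$male <- male
  env$female <- y - male
  attr(env, "generator") <- list(seed = seed, base = base,
                                 surface = surface)
  daily_series(as.data.frame(env))
}

#' Simulate a complete synthetic daily series
#'
#' Convenience wrapper: [generate_environment()] then [generate_counts()].
#'
#' @param seed integer RNG seed governing both stages.
#' @param config a [generator_config()].
#' @param surface a [true_surface()].
#' @param n_days series length; default `config$n_days`.
#' @return a [daily_series()] with environment and count columns.
#' @export
simulate_stroke_series <- function(seed = 1L, config = generator_config(),
                                   surface = true_surface(),
                                   n_days = config$n_days) {
  env <- generate_environment(config, seed = seed, n_days = n_days)
  generate_counts(env, surface = surface, config = config, seed = seed)
}
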