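# templag

Distributed lag non-linear models (DLNM) for daily ambient temperature and
emergency-department visit counts, with a fully synthetic study generator
for validating every stage of the analysis.

## The problem

Short-term effects of ambient temperature on acute events such as stroke
are non-linear in temperature and distributed over days to weeks of lag:
a cold spell raises risk gradually over the following two weeks, while
heat acts acutely within a few days. The standard design is a Poisson
time-series regression of daily counts on a *cross-basis* — a
tensor-product spline surface over temperature and lag — while controlling
for long-term trend, seasonality and day of week:

```
Y_t ~ Poisson(mu_t)
log E(Y_t) = alpha + f(Temp, lag; beta) + gamma' z_t + ns(t, 12 df/year) + eta' DOW_t
```

where `f(x, l) = sum_j sum_k beta_jk b_j(x) c_k(l)` with natural cubic
spline bases `b` (exposure dimension, df 6) and `c` (lag dimension, df 4,
constant included), summed over lags 0..14 of the last two weeks of
exposure, and `z_t` optional environmental covariates (diurnal temperature
range, relative humidity as a df-3 smooth, PM2.5, SO2). Relative risks of
a temperature `x` versus a reference `x0` (the median) at lag `l` are
`exp(c'beta)` for the contrast `c = (b(x) - b(x0)) (x) c(l)`, with
delta-method confidence intervals `c' V c`; cumulative risks sum the
contrast over a lag window. The temperature minimising the overall
cumulative risk curve is the minimum-morbidity temperature (MMT).

The package provides, behind one fitting function `dlnm_fit()`:

* `daily_series()` / `read_daily_series()` — validated daily count +
  environment tables (CSV in/out);
* `crossbasis()`, `contrast_vector()`, `cumulative_contrast()` — the
  exposure-lag design block and prediction contrasts;
* `predict()`, `cumulative_rr()`, `lag_rr()`, `find_mmt()`,
  `effect_tables()` — RR surfaces, tables and the MMT;
* `spearman_screen()`, `explore_gam()`, `select_df()` — covariate
  screening, exploratory curves, AIC selection of the basis dimensions;
* `run_single_factor()`, `run_multi_factor()`, `run_subgroups()`,
  `run_sensitivity()`, `run_all()` — the full two-stage analysis;
* `simulate_stroke_series()` and friends — a Beijing-like synthetic
  scenario with a *planted* exposure-lag surface (cold effect rising to
  lag 14, single-lag RR 1.20 and cumulative RR 2.02 at −10 °C; acute hot
  effect peaking at lag 6, RR 1.07 at 30 °C; hinge at 17 °C), so that
  estimates can be checked against a known truth.

## Worked example

```r
library(templag)

sim <- simulate_stroke_series(seed = 4)          # 730 synthetic days
fit <- dlnm_fit(sim, covariates = c("tv", "rh", "pm25", "so2"))
fit
#> Distributed lag non-linear model (poisson)
#>   outcome: stroke; covariates: tv, rh, pm25, so2
#>   cross-basis: exposure df 6 x lag df 4, max lag 14
#>   n used: 716; AIC: 4630.36; dispersion: 0.9489
#>   reference temperature: 13.33 degC

round(unclass(temp_cutpoints(sim$temp_mean)), 1)
#>     p1    p10 median    p90    p99
#>   -9.0   -3.9   13.3   25.9   29.3

lag_rr(fit, -10, lag = 14)      # extreme cold, last lag day
#>   temp l0 l1 log_rr     se   rr   lo   hi
#> 1  -10 14 14    0.2 0.0429 1.22 1.12 1.33

cumulative_rr(fit, -10, window = c(0, 14))
#>   temp l0 l1 log_rr    se   rr   lo   hi
#> 1  -10  0 14  0.677 0.214 1.97 1.29 2.99

find_mmt(fit)
#> [1] 18.9
```

Read: relative to the median temperature (13.3 °C), a −10 °C day carries
a relative risk of 1.22 (95% CI 1.12–1.33) of stroke visits 14 days
later, and sustained exposure at −10 °C over a two-week window roughly
doubles the expected daily count (cumulative RR 1.97, CI 1.29–2.99); the
fitted risk curve bottoms out near 19 °C. The generator planted RR 1.20
at (−10 °C, lag 14), cumulative 2.02, and a 17 °C hinge, so this
replicate recovers the truth within its confidence intervals.

`plot(fit)` draws the overall cumulative exposure-response curve;
`plot(predict(fit), type = "contour")` the full temperature × lag RR
surface; `run_all(sim, out_dir = "results")` writes every table
(screening correlations, single/multi-factor RR tables, subgroups,
sensitivity grid) as CSV.

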