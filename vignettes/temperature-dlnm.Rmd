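---
title: "Modelling temperature–morbidity lag structure with templag"
author: "templag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature–morbidity lag structure with templag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(templag)
```

## The model

Daily visit counts $Y_t$ are modelled as Poisson with a log-linear rate

$$\log E(Y_t) = \alpha + \sum_{l=0}^{L}\sum_{j,k} \beta_{jk}\,
b_j(x_{t-l})\,c_k(l) + \gamma^\top z_t + ns(t,\ 12\,\mathrm{df/year})
+ \eta^\top \mathrm{DOW}_t,$$

where $x_t$ is daily mean temperature, $b_1,\dots,b_{v_x}$ a natural
cubic spline basis over temperature, and $c_1,\dots,c_{v_l}$ a natural
cubic spline basis over lag $l = 0,\dots,L$. The double sum is the
*cross-basis*: a smooth surface $f(x, l)$ describing how exposure at
temperature $x$, $l$ days ago, shifts today's log rate. Summing the
surface over a lag window gives the cumulative effect of sustained
exposure. Defaults follow the published two-year emergency-visit
analysis this package operationalises: $v_x = 6$, $v_l = 4$, $L = 14$,
seasonality controlled by a natural spline in the day index with 12 df
per year, day-of-week as six indicators (Monday reference), and the
observed median temperature as the reference for all relative risks.

Two model variants matter in practice: the single-factor model
(temperature only) and the multi-factor model adding diurnal temperature
range (TV, linear), relative humidity (natural spline, 3 df), PM2.5 and
SO2 (linear). The covariate set descends from a Spearman collinearity
screen (threshold 0.6) over the full environmental panel.

### Inference

All effect estimates are linear contrasts of the fitted coefficients.
For temperature $x$ versus reference $x_0$ at lag $l$, the contrast is
$c = (b(x) - b(x_0)) \otimes c(l)$, the log relative risk $c^\top\hat\beta$,
and its variance $c^\top V c$ by the delta method — exact here, since the
contrast is linear in $\hat\beta$. Confidence intervals are computed on
the log scale with $z = 1.959964$ and exponentiated. Cumulative windows
sum contrasts before propagating the variance, which correctly accounts
for the strong correlation between neighbouring lags (the cumulative CI
is *not* a product of the single-lag CIs).

The minimum-morbidity temperature (MMT) is located by evaluating the
overall cumulative (lag 0–14) log-RR curve on a 0.1 °C grid between the
5th and 95th temperature percentiles and taking the argmin. The location
is invariant to the reference temperature, which shifts the curve by a
constant; a minimum on the grid boundary (monotone curve) is returned
with a warning rather than silently.

## Basis construction choices

**Exposure dimension.** `df` natural spline columns excluding the
constant (absorbed by the model intercept), internal knots at equally
spaced quantiles of the observed series, boundary knots at its range.
Quantiles everywhere in the package use linear interpolation of order
statistics with plotting position $(k-1)/(n-1)$ (type 7), so percentile
cutpoints, knots and summary tables are mutually consistent.

**Lag dimension.** The lag basis *includes* the constant function: the
cross-basis has no separate intercept per exposure basis function, so
without the constant the basis would vanish at its left boundary and
pin the same-day (lag 0) effect to exactly zero — a structural
misspecification, not a smoothness choice. "Lag df 4" therefore means
four columns spanning constants, with $df - 2$ internal knots. Knots are
placed at equally spaced quantiles of the integer lags $0..L$ on the
identity scale, the default of the software family this analysis
descends from when only a df is supplied; `lag_knots(..., scale =
"log")` provides the log-spaced alternative that concentrates
flexibility at short lags. We preferred the identity default after
examining what each basis can represent: with $L = 14$ and 4 df, the
log-scale basis leaves its last knot so far from lag 14 that steeply
rising late-lag responses (the cold-effect shape of interest here) are
systematically flattened at the endpoint, while identity-scale knots
(4.7, 9.3) track them closely. The exposure-df 4–8 × lag-df 2–6
sensitivity grid (`run_sensitivity()`) bounds the residual influence of
this choice.

**Incomplete rows.** The first $L$ days of a series have lagged
exposures preceding the data and are excluded from the likelihood (as
are rows with a missing exposure inside their lag window); with $L=14$
of 730 days this costs under 2% of the sample.

**Extrapolation.** Natural splines are linear beyond the boundary knots,
so prediction slightly outside the observed temperature range is
well-defined; it is allowed but warned about, since percentile contrasts
are interior by construction and only sensitivity probes should ever
reach the edges.

## Estimation

Fitting is plain Poisson IRLS (via `glm.fit`, convergence tolerance
1e-9, up to 100 iterations) with the covariance taken as the inverse
Fisher information at convergence; `family = "quasipoisson"` rescales it
by the Pearson dispersion for overdispersed counts (daily totals in the
synthetic scenario are equidispersed by construction; real
emergency-department counts often are not, which is why the option
exists). AIC uses the full Poisson log-likelihood including the
$\log y!$ term, so values are comparable across model sizes;
`select_df()` breaks AIC ties toward the smaller total df, then the
smaller exposure df. Rank deficiency is diagnosed block-by-block so the
error names the offending term rather than a column number.

## What the synthetic generator emulates

`simulate_stroke_series()` produces a two-year (default) Beijing-like
daily series with a *planted* exposure-lag surface, so every pipeline
stage can be validated against a known truth — the real visit data are
not redistributable.

**Environment.** Temperature is an annual sinusoid (mean 12.07 °C,
amplitude 16) plus a second harmonic (1.8) that lengthens the cold tail
— matching the published marginals (SD 11.8, median 13.7, P1 ≈ −10,
P99 ≈ 30) — plus AR(1) noise (marginal SD 3 °C, lag-one correlation
0.7, weather-like persistence). Humidity, diurnal range, pressure, wind
and pollutants follow seasonal patterns with marginals matched to the
published two-year summary table; PM10 and CO are constructed from
PM2.5 and SO2 so their rank correlations exceed the 0.6 screening
threshold, and pressure and ozone couple to temperature strongly enough
to be screened out, exercising the collinearity logic. Log-PM2.5
additionally couples negatively (−0.10 per °C) to the *day-to-day*
temperature residual: cold anomalies co-occur with stagnant, high-PM
episodes. This is what gives the single- versus multi-factor comparison
genuine content — with shared seasonality only, both models would
estimate the same temperature effect in expectation and "attenuation
after adjustment" would be a coin flip.

**Planted surface.** Two separable regime components hinged at the
minimum-risk temperature (17 °C): a cold component
$g_{cold}(x)\,w_{cold}(l)$ with a linear hinge in temperature and lag
weights $\log(1.20)\,(l/14)^p$, the exponent solved numerically so the
cumulative cold effect at −10 °C is exactly $\log(2.02)$
($p \approx 3.2$); and an acute hot component with a triangular lag
weight peaking at lag 6 (RR 1.07 at 30 °C) and extinct beyond lag 10.
These anchors reproduce the published effect sizes; the hinge shape and
triangle are deliberately *not* in the spline model's function class, so
recovery tests probe genuine approximation, not a self-fulfilling
parametric match.

**Counts.** The log rate adds the planted lag-sum, small conventional
covariate effects (TV +0.004/°C; U-shaped humidity term centred at 70%;
PM2.5 +0.001 per µg/m³; SO2 −0.003 per µg/m³ — directions as reported
for this kind of data, magnitudes documented here, not calibrated to any
published coefficient), a mild trend and day-of-week pattern. The
intercept is calibrated so the expected daily count is exactly 36.96;
the first 14 days get their lag history from a burn-in extension of the
temperature process (seasonal part plus a time-reversed AR
continuation), so every generated day is usable. Subgroup counts arise
by binomial thinning of the total with split probabilities (IS 0.644,
age ≥65 0.649, male 0.593) modulated on the logit scale by the cold
signal, planting the reported "ischaemic/elderly/male more
cold-susceptible" ordering.

**What it does not emulate.** Counts are conditionally independent given
the rate (no outbreak-like dependence); covariate effects and their
magnitudes are conventions; there is no measurement error in exposures,
no missing data, no holiday structure, and a single site. Passing the
recovery suite therefore demonstrates that the estimator recovers a
known surface under realistic marginals, seasonality and confounding —
not that any particular real-world estimate is correct.

## Validation design and problem sizes

The test-suite simulations use sizes chosen to make sampling noise small
relative to the tolerances while keeping a full run in the minutes
range: 200 replicates of the 730-day scenario for CI coverage and for
the type-I error of a null surface; 100 replicates for planted-effect
recovery (mean single-lag cold/hot RRs, cumulative cold RR, median MMT);
25 replicates for majority-vote directional checks (multi-factor
attenuation, cold effect maximal at the last lag, hot effect peaking
mid-window); a 10-year run for the generator's marginal calibration; and
200,000 Monte-Carlo coefficient draws to verify the delta-method
standard errors to within 1%. Oracles are independent implementations:
a truncated-power natural-spline basis, a quadruple-loop cross-basis,
Pearson-on-ranks for Spearman, and direct BFGS likelihood maximisation
for the IRLS fit.

## Known limitations

* Fixed-df smooths throughout; no penalised (automatic-smoothness)
  estimation. The exploratory per-factor curves (`explore_gam()`) use a
  df-3 smooth plus an AIC comparison against a linear term as a
  transparent stand-in for penalised-GAM curve inspection.
* The lag window ends at 14 days and the cold effect is still rising
  there, in the synthetic truth as in the published analysis; effects
  beyond the window are not identifiable from this design.
* Delta-method intervals are first-order; for the heavily non-linear
  cumulative RR at extreme temperatures they can be mildly asymmetric in
  coverage at small samples (the coverage test bounds this empirically).
* No attributable-fraction machinery, multi-site pooling, or
  case-crossover alternative.
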