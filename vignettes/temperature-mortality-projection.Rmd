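---
title: "Two-stage temperature–mortality modelling and scenario projection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage temperature–mortality modelling and scenario projection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`tempmort` implements the two-stage framework of multi-city environmental
epidemiology for estimating and projecting temperature-related excess
mortality.

**First stage.** For each location, daily all-cause death counts $Y_t$ are
modelled by a quasi-Poisson time-series regression

$$\log \mu_t \;=\; \alpha + s\big(T_t, \ldots, T_{t-L};\, \boldsymbol\gamma\big)
  + \mathrm{ns}(t;\, 8\ \mathrm{df/year}) + \mathrm{DOW}_t ,
\qquad \operatorname{Var}(Y_t) = \phi\,\mu_t ,$$

where $s(\cdot)$ is a distributed lag nonlinear model (DLNM): a
*cross-basis*, the tensor product of a natural cubic spline of temperature
(knots at the location's 10th/50th/90th percentiles, boundary knots at the
observed minimum and maximum) and a natural cubic spline of lag with
intercept over $\ell = 0,\dots,L$ with $L = 21$ days (knots equally spaced
on the $\log(\ell+1)$ scale). The natural-spline time term absorbs
seasonality and long-term trend; day-of-week indicators absorb the weekly
cycle. The fit is a log-link Poisson-family GLM by IRLS; the dispersion
$\phi$ is the Pearson $\chi^2$ over its degrees of freedom, and coefficient
covariances are scaled by $\phi$ (quasi-likelihood: point estimates are the
Poisson ones, uncertainty is inflated).

The fitted surface is *reduced* to the overall cumulative exposure–response
curve by summing lag-basis contributions over the whole window:
$\theta = M\gamma$, $V(\theta) = M V(\gamma) M'$. This curve — log relative
risk of a day's temperature cumulated over three weeks of lagged effects —
is the object all later stages work with. It is initially centered at the
location's median temperature; attribution re-centers it at the MMT
(two-pass convention).

**Second stage.** The location curves $\hat\theta_i$ with covariances $S_i$
are pooled by a multivariate random-effects meta-regression

$$\hat\theta_i \sim \mathcal N\!\big(B\,x_i,\; S_i + \Psi\big),$$

with meta-predictor row $x_i$ (intercept, standardised location mean
temperature, temperature range, log GDP per capita, optional climate-zone
indicators) and an unstructured between-location covariance $\Psi$
estimated by REML: $B$ is profiled out by generalised least squares and
$\Psi$ maximised over a log-Cholesky parameterisation by BFGS from a
method-of-moments start. Per-location best linear unbiased predictions
shrink each curve towards its meta-prediction in proportion to its sampling
uncertainty,

$$\tilde\theta_i = B x_i + \Psi (S_i + \Psi)^{-1} (\hat\theta_i - B x_i).$$

**Attribution.** The minimum mortality temperature (MMT) is the argmin of
the BLUP curve over the location's integer temperature percentiles within a
1st–99th percentile window. Daily deaths are attributed backwards:
$AF_t = 1 - e^{-\eta_t}$ with $\eta_t$ the cumulative log-RR at $T_t$
relative to the MMT, $AN_t = AF_t\, y_t$; cold sums days strictly below the
MMT, heat strictly above, and the excess-mortality (EM) fraction is
$100 \sum AN_t / \sum y_t$. Uncertainty comes from 1000 multivariate-normal
draws of the curve coefficients (MMT held fixed at its central estimate),
with empirical 2.5th/97.5th percentile intervals.

**Projection.** Scenario temperature series (per model, scenario, ensemble
member) are calibrated to the observed record by a trend-preserving
bias adjustment: per calendar month, an additive offset matching the
calibration-window monthly means, plus a residual-variance rescaling about
the (year, month) means. Because the offset is constant within a calendar
month and residuals are centered within each month cell, window monthly
means match observations exactly while month-wise long-term changes are
untouched. The baseline mortality series repeats the observed day-of-year
mean profile over 1980–2099 (constant demography by assumption). Daily EM
is recomputed on the calibrated series and the constant baseline,
aggregated to decadal fractions, differenced (control decade minus the same
run's 1980–1989; land-use scenario minus control, same decade — so the two
deltas add exactly to the scenario-minus-history change), then averaged
member → model → multimodel, and pooled regionally by total deaths (a
region's fraction is its pooled $AN$ over pooled deaths, not a mean of
location fractions).

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| exposure knots | 10/50/90 pct | percentiles | multi-city convention; linear-interpolation quantiles (type 7) because the MMT percentile depends on the definition |
| boundary knots | obs min/max | °C | natural-spline linear tails outside the data |
| lag window $L$ | 21 | days | captures slow cold effects; heat acts within days |
| lag knots | 3, log-spaced | lag scale | flexibility at short lags |
| seasonal df | 8 per year | — | standard seasonality control for daily mortality |
| IRLS tolerance | 1e-9, max 100 iter | relative deviance | conservative |
| MMT window | 1–99 pct | percentiles | avoids spline-tail instability |
| MC draws | 1000 | — | convention for empirical attribution intervals |
| calibration window | overlap with 1980–2014 | years | historical period of the scenario design |
| REML tolerance | 1e-10 | restricted likelihood | optimum stable to well below reporting precision |

# The synthetic-data generator

The restricted multi-country mortality archive and the earth-system-model
output cannot be redistributed, so the package generates data with the same
statistical anatomy and a *known* ground truth:

* daily temperature: annual harmonic + AR(1) residual (defaults: mean 14 °C,
  amplitude 8 °C, lag-1 correlation 0.7, marginal SD 3 °C — a mid-latitude
  station record);
* a U-shaped (convex) true cumulative curve, piecewise quadratic around a
  true MMT, distributed over lags by normalised geometric weights
  ($w \propto 0.75^\ell$, configurable to short-lag heat / long-lag cold
  profiles);
* counts from a gamma-Poisson mixture with mean
  $\exp(\text{baseline} + \sum_\ell w_\ell f(T_{t-\ell}))$ and variance
  `overdispersion` × mean (default 1.3). Quasi-Poisson has no generative
  form; the gamma mixture is the standard surrogate matched on the first
  two moments. Defaults give ≈30 deaths/day — a mid-size city;
* a meta-level: per-location curve parameters drawn as
  $X_i \beta_{\mathrm{true}} + u_i$, $u_i \sim \mathcal N(0, \Psi_{\mathrm{true}})$,
  with warmer locations acclimatised to higher MMTs (cross-location MMT SD
  1 °C after predictors); curvatures are clipped below at $5\times10^{-5}$
  per °C² to keep every true curve convex;
* pseudo-ESM series sharing the observed seasonal cycle and residual law
  plus a configurable additive bias, linear trend and variability scale,
  with three ensemble members by default differing only in their RNG
  substream.

A second generator (`make_meta_sample()`) draws second-stage data directly
on the curve-coefficient scale, where the pooled fixed effects and $\Psi$
are exactly known: the curve-parameter truth of `make_study()` maps
*nonlinearly* onto the coefficient scale, so coefficient-level recovery
tests need this direct route.

What the generator does **not** emulate: humidity and other co-exposures,
heat-wave added effects, mortality displacement, demographic change,
reporting gaps, shared regional climate between locations, and
country-level clustering of curves. Passing tests therefore demonstrate
correctness of the estimation and projection machinery under the model's
own assumptions, not robustness to the full messiness of observational
mortality data.

# Numerical and design choices

* **Percentile convention**: linear interpolation (R type 7) everywhere a
  quantile appears.
* **Missing data**: lags are computed on the original calendar; any day
  whose 22-day window touches a missing temperature is dropped from the
  likelihood, as is the initial burn-in.
* **MMT ties and boundaries**: ties take the lowest tied temperature; days
  exactly at the MMT count to neither cold nor heat; an argmin on the
  window edge is flagged (`boundary`), which usually indicates a curve
  monotone over the window — for such locations the spline tail beyond the
  MMT is decreasing and attribution treats it as protective, a known
  property of MMT-based attribution in climates with a weak heat limb.
* **MMT in resampling**: held fixed at the central estimate inside the
  Monte-Carlo draws (re-searching it per draw is the main alternative; the
  fixed convention is the framework's usual choice and is what the
  intervals here quantify).
* **BLUP covariance**: conditional covariance plus shrinkage-propagated
  fixed-effect uncertainty; uncertainty in $\hat\Psi$ itself is ignored
  (empirical-Bayes convention).
* **Single-level pooling**: one unstructured $\Psi$; nested country-level
  random effects are out of scope and noted as a simplification.
* **$\Psi$ positivity**: the log-Cholesky parameterisation keeps $\Psi$
  positive semi-definite by construction; the method-of-moments start
  clips negative eigenvalues.
* **Feb 29 baseline**: mean over observed Feb 29s when present, else the
  mean of the Feb 28 and Mar 1 profiles.
* **Aggregation order**: members within a model first, then models —
  fixed, so multimodel means weight models (not runs) equally; regional
  pooling is death-weighted to match the fraction's definition.
* **Seeding**: one master seed; every location, member and resampling
  stream derives a substream by stable string hashing, so adding a
  location never perturbs the others' draws and any artifact can be
  regenerated bit-identically from the manifest.

# Problem sizes

The demo configuration (`default_config()`) runs 6 locations × 5 observed
years, three pseudo-ESMs × (control + 2 land-use scenarios) × 2 members
over 1980–2099. The validation suite sizes its simulations to the property
under test: 100 seeds of 15-year records for curve recovery, 50 replicates
of 40 locations for pooled-coefficient recovery, 200 five-year datasets for
interval coverage, and 20 seeds × 6 locations × 15-year records (the
panel-typical record length) for the end-to-end warming sign check.

# Limitations

Percentile-grid MMTs inherit grid resolution; boundary-MMT locations can
attribute warming as protective (flagged, see above); the quasi-Poisson
working model ignores residual serial dependence beyond what the covariates
capture; the calibration is temperature-only (no multi-variable
consistency as in full bias-adjustment schemes); and projected intervals
reflect curve-coefficient uncertainty only — not climate-model spread,
MMT uncertainty, or baseline-mortality uncertainty.
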