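---
title: "Counterfactual carbon-flux modelling for peatland rewetting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual carbon-flux modelling for peatland rewetting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Blocking the drainage ditches of a drained peatland ("rewetting") raises the
water table and changes the site's exchange of CO2 and CH4 with the
atmosphere. Quantifying that change from eddy-covariance measurements is a
causal problem: after the intervention we can no longer observe what the
site *would have* emitted had it stayed drained. When a nearby control site
differs from the treated site even before the intervention — the usual case
— the counterfactual must come from a model.

`peatbart` implements the full chain from 20 Hz raw eddy-covariance records
to a rewetting-effect estimate with uncertainty:

1. raw-window quality control and flux computation (`ec_processing` level:
   `double_rotation()`, `block_covariance_flux()`, `wpl_ch4()`,
   `vickers_mahrt()`, `foken_wichura()`, `filter_fluxes()`);
2. driver preparation (`linear_bias_correct()`, `ensemble_gapfill()`,
   `derive_features()`, `build_driver_matrix()`);
3. a from-scratch Bayesian Additive Regression Trees (BART) engine
   (`bart()`);
4. counterfactual effect estimation (`train_period_models()`,
   `predict_actual_and_counterfactual()`, `effect_estimate()`,
   `control_validation()`);
5. budget accounting and reporting (`flux_to_carbon_mass()`,
   `annual_totals()`, `flux_budget_table()`, `growing_season_bounds()`,
   `diurnal_composite()`, `wtd_summary()`) and lateral dissolved organic
   carbon export (`annual_discharge()`, `doc_flux()`);
6. a synthetic campaign generator (`simulate_campaign()`) that produces
   two-site, multi-year campaigns with a *known* injected treatment effect,
   so every stage above is testable end to end without any field data.

## The BART model

The flux model is a sum of `m` regression trees,

$$ y_i = \sum_{t=1}^{m} g(x_i;\,T_t, M_t) + \epsilon_i, \qquad
   \epsilon_i \sim N(0, \sigma^2), $$

where each $g$ is a piecewise-constant function defined by a binary tree
$T_t$ and its leaf values $M_t$. A regularisation prior keeps each tree
weak: a node at depth $d$ splits with probability $\alpha (1+d)^{-\beta}$
(defaults $\alpha = 0.95$, $\beta = 2$), and leaf values are
$N(0, \sigma_\mu^2)$ with $\sigma_\mu = 0.5/(k\sqrt m)$ on the internally
rescaled response (default $k = 2$, so the prior puts about 95% mass of the
sum inside the observed response range). The error variance has a scaled
inverse-$\chi^2$ prior with $\nu = 3$ degrees of freedom and scale chosen so
that 90% of the prior mass lies below the sample standard deviation. In
practice only two knobs matter to users: `m` (default 50) and the leaf
scale `k`; everything else is a conventional default.

Posterior sampling is Bayesian backfitting MCMC. Per iteration, each tree in
turn receives a grow / prune / change proposal (probabilities
0.35/0.35/0.30) accepted by Metropolis–Hastings with the leaf values
integrated out analytically (conjugate normal); leaf values are then redrawn
from their conditional normal, and $\sigma^2$ from its conjugate full
conditional. Split thresholds are proposed uniformly over the midpoints
between adjacent order statistics of the observed feature values; constant
columns are never split on; proposals that would create an empty leaf are
rejected. The response is mapped to $[-0.5, 0.5]$ (mid-range centring,
range scaling) before sampling, which makes fits exactly equivariant under
affine transformations of the response.

**Chains.** `bart()` runs `n_chains` independent chains (default 4) and
pools their retained draws into one ensemble of exactly `n_draws` draws
(default 200). Pooling matters for this application: the quantity of
interest is a *sum over ~17,500 predictions* (an annual cumulative flux),
and for such long-horizon aggregates a single chain understates the
exploration component of posterior uncertainty. In our seeded recovery
experiments, pooling four chains widened the cumulative-flux intervals to
match the actual between-replicate spread and simultaneously reduced the
spread of the point estimate (chain averaging), moving 90%-interval
coverage of the known injected effect from roughly 60% to essentially
nominal. The hot loop is implemented in C++ (Rcpp); a fit with
$n = 12{,}000$, $m = 50$, four chains of 300 iterations takes a few seconds
on one core.

Predictions follow each draw's forest; out-of-range feature values simply
follow the trained splits to a terminal node (no extrapolation penalty).
Posterior summaries are the mean and the empirical 5th/95th percentiles
(linear-interpolation definition), the same summary used for all flux
budgets.

## The counterfactual design

Each site and gas gets two independently fitted models:

* a **pre-treatment model**, trained on quality-retained fluxes from
  1 Oct 2019 to the rewetting boundary (1 Oct 2021), and
* a **treatment model**, trained on 1 Oct 2021 – 1 Oct 2023.

Both are then forced with the *treatment-period* drivers. The treatment
model's draws are the best estimate of the actual fluxes (model estimates
replace measurements everywhere, so the actual and counterfactual sides are
methodologically identical); the pre-treatment model's draws are the
counterfactual. Per-draw cumulative curves in g C m$^{-2}$ use 12.011 g/mol
carbon, 1800 s records, and the sign convention that positive fluxes are
emissions to the atmosphere. The effect at an evaluation date (1 Oct 2022
and 1 Oct 2023 by default) is the difference of the posterior-mean
cumulative fluxes.

**Uncertainty combination.** The two models are fitted independently, so
their draws are not paired; the effect half-width combines the two curves'
(p95 − p5)/2 half-widths in quadrature. The draw-level difference
distribution under arbitrary index pairing is retained for diagnostics.

**Predictors.** The flux models see thirteen numeric features: shortwave
and longwave incoming radiation, air temperature, pressure, vapour pressure
deficit, wind speed, growing degree days, time since rain, and soil
temperature at 5, 10, 20, 40 and 70 cm — conceptually nine environmental
variables with the soil-temperature profile expanded over depth. Water
table depth is **deliberately excluded** and rejected by a configuration
guard: it is the causal pathway of the intervention, and a pre-treatment
model conditioned on the post-rewetting water table could not represent the
un-rewetted counterfactual. The corollary, inherited by any design of this
kind: drivers that respond to the treatment (soil temperature, VPD) leak a
little of the effect into the counterfactual, so effect estimates are
conservative in that respect.

**Control validation.** At a site with no intervention the two period
models should agree; `control_validation()` reports whether the
treatment-model cumulative estimate falls inside the pre-treatment model's
5th–95th percentile band at each evaluation date.

## Raw-flux processing choices

* Double rotation (yaw then pitch) zeroes the mean crosswind and vertical
  wind; per-sample wind speed is preserved to machine precision.
* Fluxes are block-average Reynolds covariances over 30-minute windows with
  a single block-mean removal (no detrending) and an optional constant
  time-lag compensation (default 0 samples — the closed-path lag is
  instrument-specific). A multiplicative spectral correction factor hook
  (default 1.0) stands where transfer-function corrections would be
  applied.
* The open-path CH4 channel gets the standard WPL density correction
  $F = F_0 + \mu(\rho_m/\rho_d)E + (1+\mu\sigma)(\rho_m/\bar T)\,H/(\rho c_p)$
  with $\mu$ the dry-air/water molar mass ratio and $\sigma = \rho_v/\rho_d$.
* Raw-data screening follows the classic 1997 battery with its published
  defaults: spikes are runs of at most 3 samples beyond 3.5 local (5-min
  moving window) standard deviations, hard-flagging above 1% of the record;
  dropouts are runs stuck in one distribution bin for more than 10% of the
  record; amplitude resolution fails when over 70% of 100 bins across
  mean ± 3.5 sd are empty; |skewness| > 2 or kurtosis outside [1, 8]
  hard-flags; and a Haar half-window mean difference above 3 total standard
  deviations flags a discontinuity.
* Stationarity uses the relative deviation between the 30-min covariance
  and the mean of six 5-min covariances, collapsed to flags
  {0: < 30%, 1: < 100%, 2: otherwise}; only flag-0 records with mean
  horizontal wind ≥ 1.5 m s$^{-1}$ and a clean screening battery are
  retained. The integral-turbulence-characteristics sub-test is not
  implemented; the stationarity statistic alone determines the flag.

## The synthetic campaign generator

The generator is the package's laboratory: it fixes the statistical
structure the flux models must learn, with every "true" quantity exported
so recovery tests never re-derive it.

* **Drivers.** Each meteorological variable is mean + seasonal harmonic +
  diurnal harmonic + AR(1) noise (air temperature: 3.5 °C mean, 9 °C
  seasonal and 3.5 °C diurnal amplitude, AR(1) 0.95). Soil temperatures are
  exponentially damped (100 cm damping depth), low-pass filtered copies of
  the air-temperature anomaly, giving the observed smoothing, lag and
  amplitude decay with depth. Precipitation is a two-state Markov chain
  with exponential event depths tuned to ≈ 950 mm yr$^{-1}$, the regional
  norm. Water table depth gets its own seasonal harmonic around 30 cm.
* **Fluxes.** CO2 net exchange is Q10 respiration (2.5 µmol m$^{-2}$
  s$^{-1}$ at 10 °C, Q10 = 2.2) minus a rectangular-hyperbola light
  response (initial slope 0.025, saturation 5.5 µmol m$^{-2}$ s$^{-1}$),
  which integrates to a small net source of roughly +20 g C m$^{-2}$
  yr$^{-1}$ — the regime of a forestry-drained boreal peatland. CH4 is
  log-linear in 20 cm soil temperature and water table depth minus a small
  constant uptake, permitting weak non-growing-season uptake; it integrates
  to ≈ 3 g C m$^{-2}$ yr$^{-1}$. Gaussian observation noise: 2 µmol (CO2),
  5 nmol (CH4).
* **Treatment.** Multiplicative respiration/uptake/CH4 changes plus a
  water-table shift, ramping linearly over 60 days from the rewetting date
  (1 Oct 2021); the default magnitudes (respiration ×1.06, uptake ×0.99,
  CH4 ×1.15, water table −9 cm) produce two-year cumulative effects of a
  magnitude realistic for boreal rewetting (~90 g C CO2, ~4 g C CH4). Factual and
  counterfactual series share the noise realisation and are bitwise equal
  before the rewetting date.
* **Gaps** arrive in runs (a mixture of short glitches and multi-day
  blocks) at a target fraction, default 30%, typical of eddy-covariance
  campaigns.
* **Raw windows** are 36,000-sample (20 Hz × 1800 s) Gaussian turbulence
  with near-exact target w'–scalar covariances, configurable mean wind,
  anemometer tilt, and planted spikes/dropouts at recorded indices.

What the generator does **not** emulate: radiative transfer and realistic
diurnal-solar geometry, snow, storm-scale turbulence intermittency,
instrument drift, u*-filtering physics, or correlated multi-variable driver
shocks. Passing recovery tests therefore demonstrate that the estimation
machinery is unbiased and calibrated *under the stated statistical
structure*, not that any field campaign meets that structure.

## Numerical and design choices

* Timestamps label the **end** of each 30-minute interval (eddy-covariance
  community convention); hydrological years run 1 Oct – 30 Sep with true
  calendar arithmetic (2019/20 has 366 days).
* Carbon mass uses 12.011 g mol$^{-1}$; the choice versus 12.0 affects the
  fourth digit.
* Growing degree days use base 5 °C with a 1 January reset; the dry-spell
  clock resets at ≥ 0.1 mm per half-hour; VPD uses the Magnus saturation
  formula.
* The growing season is the longest run of negative 7-day-smoothed daily
  NEE that is at least 14 days long **and contains midsummer (1 July)**;
  the anchor keeps winter sink artefacts from qualifying. Season bounds are
  therefore defined only up to the smoothing half-window (±3 days).
* Gap filling of drivers and ET uses the package's own tree ensemble in
  posterior-mean mode rather than a separate random-forest implementation:
  one tree codebase, statistically equivalent behaviour for the filling
  task, exact preservation of observed records.
* The annual water balance is a single-bucket model,
  $Q = \max(0, P - ET - \Delta S)/1000 \times A$; DOC export applies a
  flow-unweighted mean of grab-sample concentrations. Back-solving the
  catchment area from published (Q, DOC, flux) triples is exposed as a
  consistency check — if implied areas drift between years, concentrations
  were flow-weighted or the discharge integration differed.
* The ± half-widths on published annual budgets are treated as half of the
  (p95 − p5) posterior interval throughout; the quadrature rule reproduces
  published combined uncertainties from their components (e.g. half-widths
  15 and 47 combine to ≈ 49.3).

## Problem sizes used in the shipped tests

The test suite and the acceptance script exercise the counterfactual
machinery on campaigns scaled to one-year pre-treatment and treatment
periods (≈ 17,500 half-hours each, ≈ 12,300 training records per period
after 30% gaps), ten seeded replicates each for the null and the injected
effect, with `m = 50`, four chains of 250 + 50 iterations and 200 retained
draws. These sizes are the package's chosen reference experiment: large
enough that interval calibration and bias are meaningful, small enough to
re-run routinely. The tree-ensemble benchmark uses the standard five-term
interaction function at n = 500 with ten features.

## Known limitations

* The sampler is classic backfitting MH (grow/prune/change); it does not
  implement particle-Gibbs tree updates, heteroskedastic error models, or
  variable-importance machinery.
* Effect uncertainty combines independent-model half-widths in quadrature;
  if the two models' errors were correlated (shared drivers), the true
  width could differ.
* Counterfactual validity rests on drivers unaffected by the treatment;
  soil temperature and VPD violate this mildly, water table depth would
  violate it fatally and is excluded.
* The growing-season rule and the bucket water balance are deliberately
  simple operationalisations; neither claims to reproduce any specific
  published season table or discharge series.
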