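---
title: "Estimating and projecting under-5 and neonatal mortality with childmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and projecting under-5 and neonatal mortality with childmort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

National under-5 mortality (U5MR) and neonatal mortality (NMR) are
monitored against the SDG 3.2 targets (25 and 12 deaths per 1000
livebirths by 2030), but only about a third of countries have vital
registration (VR) systems complete enough to read the rates off directly.
Everywhere else the evidence is a patchwork of full-birth-history (FBH)
survey series, summary-birth-history (SBH) census estimates, and sample
registration, each with its own sampling error and systematic bias, often
ending several years before the year for which estimates are needed.
`childmort` implements the full estimation chain for this setting:
multi-source bias-adjusted trend estimation for U5MR, ratio-based NMR
estimation, conversion of rates to death counts, scenario projection to
2030, and SDG progress classification — together with a synthetic-world
generator so that every stage can be tested end to end against a known
truth.

## The trend model for U5MR

All modelling is on the log-rate scale. For country $c$, the true log
U5MR trajectory is a cubic B-spline with knots every 2.5 years (clamped
at the period boundaries, so the basis is a partition of unity), and a
first-order random-walk prior on the coefficients:
$$\log u_c(t) = \sum_k B_k(t)\,\alpha_{c,k},\qquad
  \alpha_{c,k} \sim \mathcal N(\alpha_{c,k-1}, \sigma_\alpha^2).$$
The random walk penalises first differences, so the fit is smooth where
data are weak and flexible where they are dense. The knot spacing and
penalty order are fixed package choices made for testability.

An observation $y_i$ (log observed rate) from series $j(i)$ of source
type $s(i)$ is modelled as the true value times an error multiplier,

$$y_i = \log u_{c(i)}(t_i) + \beta_{s(i)} + u_{j(i)} + \varepsilon_i,
  \qquad \varepsilon_i \sim \mathcal N\!\big(0,\; se_i^2 + \omega_{s(i)}^2\big),$$

with three error components:

* $\beta_s$ — the mean log bias of source type $s$, pooled across all
  countries in the fit. VR is the identifiability anchor,
  $\beta_{VR} = 0$: without a fixed reference the overall level and the
  biases are confounded.
* $u_j$ — a series-level random offset, $u_j \sim \mathcal N(0, \tau_s^2)$,
  pooled by source type and absent for the anchor type. A whole survey
  series can sit above or below the truth by a common factor; treating
  that divergence as independent per-observation noise would let it
  average away and understate the level uncertainty of survey-only
  countries.
* $\varepsilon_i$ — the reported sampling error $se_i$ plus a source-type
  non-sampling standard deviation $\omega_s$, both on the log scale.

Sampling is MCMC via JAGS (4 chains by default), with the `glm` module
loaded for block updating: the spline coefficients, biases and series
offsets form a strongly correlated normal sub-graph on which single-site
Gibbs mixes poorly. The series-offset precision carries a conjugate gamma
prior (shape 1.5, rate 0.015, putting the offset SD loosely around
0.05–0.2) for the same reason: a boundary-avoiding prior that JAGS can
Gibbs-sample; half-normal SD priors left the variance stuck in a funnel.
Convergence is checked with the Gelman–Rubin statistic on every monitored
parameter (excluding anchored constants); a fit with max $\hat R > 1.05$
raises an error rather than returning silently, and the pipeline driver
retries once with 4-fold longer chains before giving up.

Uncertainty is reported as 90% equal-tailed posterior intervals
(5th/95th percentiles), the convention for these indicators, where 95%
intervals are too wide to be informative.

### Extrapolation beyond the data

Many countries' last datapoint precedes the common estimation endpoint by
several years. Inside `fit_world`, years after a country's last
observation (and, symmetrically, before its first) are replaced by a
trend-blended continuation of each posterior draw: for the $k$-th
extrapolated year the per-year log decrement is
$\rho^k a_{draw} + (1-\rho^k)\,a_{global}$, where $a_{draw}$ is the
draw's own average decline over the trailing 10 observed years,
$a_{global}$ is the cross-country median decline, and $\rho = 0.9$, so
the country's own trend dominates early and the global trend takes over.
A per-year innovation (SD 0.03 on the log scale, the per-year diffusion
implied by the trend family's random-walk increments) widens the
intervals with extrapolation length. Both $\rho$ and the innovation SD
are arguments of `extrapolate()`; setting the SD to 0 gives a
deterministic continuation of each draw.

## The ratio model for NMR

NMR is not fitted directly. The package models the ratio
$R(c,t) = \mathrm{NMR}/(\mathrm{U5MR} - \mathrm{NMR})$ as
$R = W(u) \times P_c(t)$:

* $W(u)$ — the expected ratio given the country-year's U5MR, a
  log-quadratic least-squares fit pooled over all observed country-year
  pairs. Its negative slope encodes the global regularity that the
  neonatal share of under-5 deaths rises as overall mortality falls.
* $P_c(t)$ — a country multiplier, $\log P_c$ a B-spline with a
  random-walk prior centred at zero (prior mean $P = 1$), fitted to the
  country's NMR observations. Countries without NMR data follow the
  global relation, with the cross-country residual spread of the $W$ fit
  as their level uncertainty.

NMR observations first pass through the U5MR fit's error model
(`debias_observations`): values are divided by the estimated source-type
bias multiplier and their standard errors inflated by the estimated
non-sampling and series-divergence components, then propagated to the
ratio scale by the delta method ($\partial\log R/\partial \log \mathrm{NMR}
= 1 + R$). Skipping this correction makes the NMR intervals ignore survey
bias and under-cover markedly.

Draws of NMR are derived as $\mathrm{NMR} = \mathrm{U5MR} \cdot R/(1+R)$,
pairing U5MR and ratio draws one to one. Because $R/(1+R) < 1$ for any
positive $R$, **every** NMR draw is strictly below its paired U5MR draw —
the ordering is a property of the transform, not a constraint that can
fail. SBH series never contribute NMR observations (summary birth
histories cannot yield direct neonatal estimates).

## From rates to deaths: the birth-week cohort method

Death counts are computed by exposing 52 equal birth-week cohorts per
birth year (seeded at week midpoints) to calendar-year- and age-specific
mortality through their first five years. Rates convert to a
two-segment piecewise-constant hazard per calendar year:
$$h_{neo} = \frac{-\log(1 - \mathrm{NMR}/1000)}{28/365.25}, \qquad
  h_{post} = \frac{-\log\frac{1 - \mathrm{U5MR}/1000}{1 - \mathrm{NMR}/1000}}{5 - 28/365.25},$$
so that a cohort under a constant schedule dies with probability
NMR/1000 by day 28 and U5MR/1000 by age 5 exactly. Each cohort's five
years are split at the neonatal age boundary and at every calendar-year
boundary; because the hazard is constant within each (year, age-segment)
cell, integrating interval by interval is exact, and the implementation
agrees with a daily-resolution microsimulation to about $10^{-5}$
relative (the test suite asserts 0.5%, the accuracy claim made for the
method; conservation of cohort members holds to $10^{-15}$ relative).
Deaths are allocated to the calendar year in which they occur and summed
by age group (neonatal vs 1–59 months). Cohorts born within five years
of the reporting end reuse the last year's schedule for their remaining
exposure; cohorts born before the first schedule year reuse the first.
The production systems in this field split the 1–59-month range further
using infant mortality; with only U5MR and NMR available the two-segment
hazard is the declared package choice, and the microsimulation oracle
bounds its internal consistency, not that approximation.

Uncertainty intervals for deaths re-run the cohort engine per posterior
draw with livebirths held fixed — the intervals reflect rate uncertainty
only. Regional and global intervals sum draws across countries first
and take quantiles second; sums of quantiles are not quantiles of sums.

## Scenarios 2020–2030

Four scenarios project each country from its 2019 estimate, using the
annual rate of reduction $\mathrm{ARR} = \ln(r_{t_1}/r_{t_2})/(t_2-t_1)$
measured over 2010–19 on posterior medians:

* **constant_2019** — rates held flat;
* **current_trends** — exponential continuation at the 2010–19 ARR,
  held flat if the ARR is negative, floored at the lowest observed rates
  (U5MR 1.7, NMR 0.85 per 1000);
* **achieve_sdg** — countries neither at nor on track for the target
  follow the constant required ARR, $\ln(r_{2019}/\mathrm{target})/11$,
  hitting 25 (U5MR) or 12 (NMR) exactly at 2030; achieved/on-track
  countries keep their current-trends path;
* **achieve_hic** — the same construction toward the 2019 high-income
  averages 5.0 and 2.9.

NMR paths are additionally capped at 0.79 times the projected U5MR (the
highest ratio observed in a country with reliable vital registration),
applied year by year after the scenario rule — the two indicators are
projected independently and then reconciled, the literal reading of the
method. "On track" means the current-trends 2030 value meets the target.
An optional per-country-year rate adjustment input allows crisis
mortality to be removed before the ARR window; the adjustments
themselves are out of scope. Projected deaths use the same livebirths in
every scenario, so scenario differences are averted deaths.

Progress classification bands countries needing acceleration by
required/current ARR (current ARR floored at $10^{-6}$, so stagnating
countries land in the "at least triple" band), and reports the
current-trends achievement year, censored as ">2099".

## The synthetic world

`generate_world()` creates the test-bed the package is validated on: by
default 25 countries over mid-years 1985.5–2019.5. True log U5MR is an
exact exponential decline (level ~ U(20, 200) per 1000, ARR ~ U(0.005,
0.05)) plus a zero-mean spline wiggle from the same family the model
fits (random-walk increments, SD 0.05 per 2.5-year knot); true NMR comes
from the ratio relation $\log R = 2.0 - 0.6 \log u$ times a smooth
country multiplier. About 40% of countries get a continuous VR series;
the rest rely on 2–3 FBH surveys (periodic, ending 0–5 years before the
endpoint) and occasionally an SBH census. Biases are characteristic of
the source type (VR/SRS 1.0, FBH 0.95, SBH 0.90) with small per-series
lognormal scatter (SD 0.03) — the structure the data model's mean-bias
and series-divergence terms adjust for. Sampling SDs are 0.025 (VR),
0.07 (FBH) and 0.10 (SBH) on the log scale, with unreported extra noise
0.01/0.03/0.05. Livebirths follow compound growth with mild noise.

What the generator deliberately reproduces: overlapping series with
conflicting levels, source-type bias, gaps of several years before the
estimation endpoint, NMR < U5MR by construction, and the negative
ratio–level relation. What it does not reproduce: indirect SBH
estimation mechanics (SBH series are represented only by their bias and
error signature), HIV/crisis mortality shocks, non-lognormal outliers,
and within-country subnational heterogeneity. Passing recovery tests on
this world therefore demonstrates internal consistency of the estimation
chain under its own assumptions, not robustness to real-data pathologies
outside them.

Every stochastic step is seed-deterministic: the same master seed
reproduces the world, the MCMC chains (per-chain JAGS RNG seeds derived
from it) and the extrapolation innovations bit for bit.

## Validation scale and numerical choices

The recovery checks fit a 50-country world (so coverage is estimated
over at least 50 replicate countries) with 4 chains, 2000 burn-in and
2000 sampling iterations thinned by 4 — about two minutes on one core;
the unit tests use lighter chains for single-country properties. On that
world the posterior-median log-U5MR RMSE is ≈ 0.07 with 90%-interval
coverage ≈ 0.92 (the suite asserts ≤ 0.08 and [0.85, 0.95]). Death
intervals default to 200–250 draws through the cohort engine per
country. Reported rates are rounded to one decimal only at the reporting
layer; comparisons and intermediate files keep full precision (CSVs
store four decimals). Degenerate inputs are rejected rather than
repaired: non-positive rates, NMR ≥ U5MR, constant-U5MR input to the
$W$ fit, spans too short for the spline support, unknown scenario or
source types.

## Known limitations

* The bias adjustment is identified by the VR anchor plus cross-country
  pooling; a world in which *every* series of every type shares one bias
  direction, with no anchor, is not identifiable — the model then
  returns the consensus level with honest extra uncertainty.
* The series-divergence mechanism is a random intercept per series; the
  production notion of divergence between overlapping series over time
  (a covariate in the original data model) is represented only through
  this offset plus the extra-variance term.
* Backcast and extrapolated years rest on the trend-blend assumption;
  structural breaks (conflict, epidemics) in data-free years are
  invisible to it.
* Group rates aggregate by births weighting, which is exact when member
  rates are equal and second-order accurate otherwise; the alternative —
  inverting the cohort model at the group level — differs by well under
  display precision for realistic heterogeneity.
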