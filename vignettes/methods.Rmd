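---
title: "Methods: small-area self-harm incidence and hospital-cost estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area self-harm incidence and hospital-cost estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Hospital-presenting self-harm (intentional self-poisoning or self-injury,
irrespective of suicidal intent) is monitored comprehensively in only a
handful of English sentinel centres. National administrative data capture
mainly admitted episodes and therefore understate the true presentation
burden substantially. `selfharmcosts` implements a sentinel-extrapolation
pipeline that turns episode-level monitoring data from three centres — two
with full episode-level hospital cost data, one without — into estimates of
the number of self-harm presentations and their general-hospital costs for
every health-commissioning area, with Monte-Carlo uncertainty on the cost
totals and two univariate sensitivity calibrations.

The pipeline has five stages:

1. **Rate estimation.** Presentation rates per person-year are computed by
   single year of age and gender as sentinel episode counts divided by the
   sentinel catchment population. Events are episodes, not patients: a
   patient presenting three times contributes three events.
2. **Extrapolation.** Each cell rate is multiplied by the corresponding
   population of every area, giving fractional expected presentation counts
   per (area, age, gender) cell; rounding happens only when formatting
   reports.
3. **Cost modelling.** Episode costs from the two cost-observed centres are
   regressed on gender, age, psychosocial assessment, hospital admission
   and self-harm method with a Gamma generalised linear model with log
   link; standard errors use the one-way cluster-robust sandwich estimator
   with patients as clusters. The fitted coefficients predict costs for the
   cost-missing centre's episodes, rescaled by the ratio of geographic
   price indices (Market Forces Factor, MFF).
4. **Aggregation and uncertainty.** A mean-cost table by age year and
   gender multiplies into the incidence table to give area cost totals.
   Coefficient vectors are then drawn repeatedly from a multivariate normal
   with the cluster-robust covariance, the predicted-cost component is
   recomputed per draw, and percentile intervals of the resulting totals
   summarise the uncertainty.
5. **Sensitivity.** Two univariate calibrations rescale the incidence (and
   hence costs): one by the ratio of each area's gender-specific
   age-standardised suicide rate to the sentinel-centre average, one by a
   rurality factor reflecting lower rural presentation rates.

## The cost model

For episode $i$ of patient $p$ with covariate row $x_i$ (intercept, male
indicator, age in years, assessed indicator, admitted indicator, and
indicator contrasts for self-injury and combined methods against
self-poisoning, the modal method class),

$$\mathbb{E}[y_i] = \mu_i = \exp(x_i^\top \beta), \qquad
y_i \sim \mathrm{Gamma}(\nu,\ \nu/\mu_i),$$

fitted by the quasi-score equations
$\sum_i x_i (y_i - \mu_i)/\mu_i = 0$ (so an intercept-only fit reproduces
the arithmetic sample mean exactly), with covariance
$\widehat{\mathrm{V}}(\hat\beta)$ from the patient-clustered sandwich
estimator (`sandwich::vcovCL`). Age enters as a single continuous per-year
slope: the minimal reading of "adjusted for age", with single-year cost
cells later allowing any residual non-linearity to show up in the mean-cost
table rather than the model.

Two preprocessing rules precede fitting:

* **Assessment-cost imputation.** Where a centre's finance export excludes
  the psychosocial assessment, assessed episodes receive the published unit
  cost: £392 for patients younger than 18 years, £228 for adults (2013/14
  prices). The imputation is per assessed episode and idempotent (a flag
  flips once the cost is included). Whether the original adjustment was per
  episode or per patient is not documented; per-episode is used because
  assessment is recommended at every presentation.
* **Non-positive costs.** Zero or negative recorded costs (possible in
  finance exports) are excluded from fitting with a logged count, since the
  Gamma support is positive; such episodes still receive predicted costs
  for aggregation.

### Cross-centre transfer

Predictions for the cost-missing centre are
$\hat y = \exp(x^\top \hat\beta) \cdot \mathrm{MFF}_{target} /
\overline{\mathrm{MFF}}_{fit}$, where $\overline{\mathrm{MFF}}_{fit}$ is the
episode-weighted mean index of the two fitting centres. This convention
makes a flat price surface (all indices equal) a strict no-op, and doubling
the target index exactly doubles every prediction. Observed costs are never
rescaled — they already embody their local price level.

### The mean-cost table

Mean cost per (age year, gender) cell is the arithmetic mean of the
analysis costs of the contributing episodes. By default
(`mean_cost_mode = "observed_plus_predicted"`) the analysis cost is the
(imputed) observed cost for the cost-observed centres and the model
prediction for the cost-missing centre; a `"predicted"` mode uses model
predictions throughout (useful for calibration studies, below). Cells with
fewer than `cost_cell_min_n = 5` episodes take their enclosing 10-year band
mean (`pooled_flag = TRUE`); a band with no episodes falls back to the
gender-wide mean. Ages at or above `age_cap = 90` pool into a single top
band everywhere (rates, costs, populations), because single-year cells
empty out at high ages.

## Monte-Carlo uncertainty

Each of `mc_iterations = 10000` iterations draws
$\beta^* \sim \mathcal{N}(\hat\beta, \widehat{\mathrm{V}}(\hat\beta))$,
recomputes predicted costs, the mean-cost table and all totals, and the
2.5th/97.5th percentiles of the draws form the 95% interval. Choices worth
stating explicitly:

* Percentile rather than normal-approximation intervals: the national total
  is a positive nonlinear functional of $\beta$, so its draw distribution
  can be asymmetric; percentile intervals are assumption-light.
* Only cost-model uncertainty is propagated. The incidence table and the
  observed-cost contributions are held fixed across iterations, because the
  drawn quantity is the regression coefficient vector; sampling error in
  the rates and in the imputation constants (£392/£228) is deliberately not
  simulated.
* A covariance that fails positive semi-definiteness (numerically) is
  projected onto the nearest PSD matrix with a warning; a zero covariance
  collapses the interval onto the point estimate exactly.
* Draws are processed in chunks of 200 iterations as one matrix product per
  chunk, so 10,000 iterations stay inside modest memory.

### Interval calibration

`mc_calibration()` checks the intervals in nested simulation: many
synthetic worlds, each fitted and propagated, scoring how often the
national-cost interval covers the generative expectation. The study design
isolates the uncertainty the interval claims to carry: worlds use
`mean_cost_mode = "predicted"`, the incidence table is fixed at its
closed-form expectation, and patient effects are switched off so the
generating model coincides with the fitted one. Under that design the only
estimation error flowing into the total is $\hat\beta - \beta$, which is
exactly what the draws emulate; residual case-mix sampling noise in the
cell means (not propagated) keeps expected coverage slightly below nominal.
The shipped checks use 200 worlds of ~2,000 episodes with 1,000 iterations
each, which runs in well under a minute and bounds the binomial error on
the coverage estimate at about ±1.5 percentage points.

## Sensitivity calibrations

* **Suicide rates.** factor(area, gender) = area ASR ÷ mean ASR of the
  three sentinel areas (same gender), applied uniformly across ages within
  a gender. A zero sentinel average is an error.
* **Rurality.** Fully rural areas are taken to present about 31% (male) /
  26% (female) less than urban areas. The default `"fraction"` mode
  interpolates linearly: factor = 1 − rural_fraction × reduction, so a
  half-rural area gets factors 0.845/0.87. Whether the original adjustment
  used binary area classes or population fractions is not documented, so a
  `"binary"` mode (threshold 0.5) is available behind the configuration;
  the fraction form is the default because English commissioning areas are
  rarely purely rural or urban.

Each calibration is univariate — exactly one factor table at a time, as in
the headline analyses; chaining both is mechanically possible but
corresponds to no reported analysis. Adjustment commutes exactly with
aggregation (it is a cellwise rescaling), and adjusted runs reuse the same
Monte-Carlo machinery and seed so adjusted totals also carry intervals.

### National patient counts

National patient (as opposed to episode) totals are obtained by scaling
episode totals by the sentinel patients-to-episodes ratio per gender. The
original method behind the published patient figure is not documented; the
ratio scaling is this package's declared approximation and is exact when
repeat behaviour in the sentinel centres matches the country.

## The synthetic-data generator

Because the underlying patient-level data are confidential, the package
ships a generator whose defaults emulate the study conditions and whose
ground truth is known in closed form:

* **Three centres** with distinct case-mixes: psychosocial assessment
  probabilities 0.73/0.60/0.50, admission 0.78/0.55/0.37, self-poisoning
  shares 0.70/0.76/0.63, female shares 0.60/0.60/0.55, and ~3,000/2,500/
  4,500 episodes (the `faithful` preset, ~10,000 sentinel episodes in
  total; `tiny` is one tenth for smoke runs). Centre C plays the
  cost-missing role.
* **Ages** are drawn from gender-specific band mixtures (modal band 40–49
  for men, 19–29 for women), uniform within band, because only banded
  distributions are published; band weights are shared across centres.
* **Repeat episodes.** Each patient's episode count is geometric with
  continuation probability `repeat_prob = 0.15`: after any episode the same
  patient re-presents with that probability. This gives closed forms used
  by the tests (expected episodes per patient $1/(1-p)$; expected share of
  episodes belonging to repeat patients $1-(1-p)^2$) and realistic repeat
  shares of roughly one in four episodes.
* **Costs** follow the exact model the costing module fits:
  Gamma with mean $\exp(x^\top\beta + u_p)\cdot \mathrm{MFF}_{centre}$,
  shape 1.5 (coefficient of variation ≈ 0.8, typical of episode-level
  hospital costs), patient random intercept $u_p \sim
  \mathcal{N}(0, 0.1^2)$ on the log scale shared across a patient's
  episodes. With `patient_effect_sd = 0` the generator and the fitted
  model coincide, enabling unbiased-recovery and coverage tests without
  misspecification. The Gamma family is the fitted family by construction —
  the real data's distribution beyond that choice is unknown, and this
  assumption is flagged here deliberately.
* **Geography**: the three centre areas plus 12 synthetic areas spanning
  price indices 0.95–1.15, rural fractions 0–0.8 and suicide-rate
  gradients; pyramids are drawn around a common age profile so that seeds
  change the pyramids but not the structure. The sentinel catchment is the
  union of the three centre areas. `price_variation = FALSE` flattens every
  MFF to 1.
* An option (`deduct_assessment_centre`) exports one centre's costs net of
  the assessment unit cost (floored at £1) to exercise the imputation
  stage; because of the floor the round trip is only approximate for the
  cheapest episodes, so recovery tests keep it off.

What the generator does **not** emulate: seasonal and weekday structure,
ethnicity and drug-class detail (carried only as optional pass-through
columns), genuine spatial correlation between neighbouring areas,
deprivation gradients in the rates themselves, and any misspecification of
the cost model family. Passing tests therefore demonstrate the estimator
machinery — not that the Gamma log-link model is right for real costs.

`truth_report()` returns the closed-form expected presentations and costs
per cell given a realised geography (expectations marginalise the
case-mix, the log-normal patient effect via $e^{\sigma^2/2}$, and centre
price levels), and is the oracle against which end-to-end estimates are
compared.

## Numerical and testing choices

* GLM convergence uses a deviance tolerance of 1e-12 so the fitted
  quasi-score vanishes to near machine precision; singular designs abort
  with the offending columns named rather than silently dropping terms.
* Coefficient-recovery checks run at ~22,000 fitting episodes: the rarest
  covariate class (combined self-poisoning and self-injury, ~5% of
  episodes) then pins its coefficient with a standard error ≈ 0.025, well
  inside the asserted ±0.05 — at a few thousand episodes the assertion
  would be a coin flip on that coefficient rather than a test of
  correctness.
* Wald-coverage checks (500 replications) use ~4,400 fitting episodes per
  replication for the same reason: sandwich intervals undercover for
  sparse dummies in small samples regardless of implementation.
* The robust-vs-naive standard-error ordering is asserted in a regime where
  within-patient correlation dominates episode-level noise (Gamma shape 10,
  patient SD 0.5, repeat probability 0.5); with heavy-tailed episode noise
  the sandwich estimate is itself noisy and the ordering is only an
  expectation, not a per-sample guarantee.
* Rate-recovery checks use `repeat_prob = 0` so cell counts are
  independent and binomial standard errors are the right yardstick;
  repeat patients inflate count variance by the cluster factor.
* All stochastic stages take explicit seeds; identical seeds give
  byte-identical written outputs, recorded in a run manifest with a
  configuration hash.

## Known limitations

* Incidence carries no uncertainty: intervals reflect cost-model
  coefficients only, so they understate total uncertainty where sentinel
  sampling error matters.
* The sentinel rates are transported unchanged apart from the two
  calibrations; no spatial smoothing or deprivation adjustment is applied.
* The patients-from-episodes ratio assumes national repeat behaviour
  matches the sentinel centres.
* Cells with populations but no sentinel rate (possible under age-cap
  mismatches) receive rate zero with a logged flag — conservative and
  transparent, but a downward bias if such cells are genuinely at risk.
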