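---
title: "Methods: time-stratified case-crossover analysis of PM2.5 and mortality with segregation modifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-stratified case-crossover analysis of PM2.5 and mortality with segregation modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcrossover)
```

## The design

`pmcrossover` implements the full analytical pipeline of a
time-stratified case-crossover study of short-term fine particulate
matter (PM2.5) exposure and daily mortality, with effect modification by
decedent race, neighborhood racial composition, and two census-derived
segregation indices. The case-crossover design compares each decedent's
exposure on the day of death (the *case day*) with their own exposure on
nearby *referent days*; because the comparison is within person, all
time-invariant personal and neighborhood confounders cancel by design.

Referent days are chosen time-stratified: every 3rd day before and after
the case day, within the same calendar month and year
(`select_referents()`). Equivalently, the referent stratum is the set of
all days of the month sharing the case day's day-of-month residue modulo
3. Fixing strata by calendar (rather than relative to the case day) is
what makes the scheme free of overlap bias: every case day in the same
(year, month, residue) class sees exactly the same day set, so the
conditional likelihood below is a genuine likelihood. Each stratum has
between 8 and 10 referents (8 only in February).

## The conditional likelihood

Each matched set contributes the probability that the case day is the
observed one among its stratum days, a softmax in the linear predictor:

$$\ell(\beta) \;=\; \sum_s \Big[ x_{\text{case},s}^\top\beta \;-\;
  \log \sum_{j \in s} \exp\!\big(x_j^\top\beta\big) \Big].$$

`conditional_loglik()` evaluates this with per-set max subtraction
before exponentiation, so the result is finite for every finite `beta`;
exact analytic gradients and Hessians are available on request.
`fit_clogit_design()` maximizes it by Newton–Raphson with step-halving,
starting from `beta = 0`, declaring convergence when the gradient
max-norm falls below `1e-8` (at most 50 iterations). The covariance is
the inverse negative Hessian at the optimum.

Two failure modes are detected explicitly rather than silently:

* **Inestimable columns.** Any covariate constant within every matched
  set — in particular the *main effect* of any person/place modifier
  (race, percent black, RRS category, IRD) — cancels from every softmax
  and is not estimable. The fitter centers the design within sets first
  and raises a rank-deficiency error naming the offending column. This
  is why all modifier models below contain only exposure-by-modifier
  *interaction* terms.
* **Separation.** If the likelihood is monotone (e.g., the case day has
  the largest exposure in every set), the coefficient diverges; the
  fitter raises an error naming the column once a standardized
  coefficient exceeds 12.

The adjustment set mirrors what the matching cannot control within
month: six day-of-week indicators (Sunday reference) and linear plus
quadratic lag-window temperature. Temperature is centered at the sample
mean before squaring, which reduces collinearity between the linear and
quadratic columns; this is a pure reparameterization and leaves the
PM2.5 coefficient untouched (tested).

## Exposure assignment and windows

Exposure comes as a daily gridded product (long CSV: cell, date, PM2.5
in µg/m³, temperature in °C). Each record is assigned the cell nearest
its residential coordinates once, by great-circle (haversine) distance;
distance ties — equal to within one micron, which absorbs floating-point
jitter of the spherical formula — go to the lexicographically smallest
cell id, so assignment is deterministic and permutation-invariant. The
main exposure is the two-day mean of the current and previous day
(`lags = c(0, 1)`); single-lag windows (`lags = 0`, `lags = 1`) are the
sensitivity analyses. Temperature uses the same window as PM2.5. A
window is defined only when all constituent daily values exist: missing
days are never imputed — an undefined referent-day window drops that
day from its set, an undefined case-day window drops the whole record,
and both are counted in the build log. This preserves the validity of
the conditional likelihood, since exclusion depends only on exposure
availability, not on outcomes.

A second sensitivity analysis restricts to days in compliance with the
24-hour National Ambient Air Quality Standard:
`restrict_below_threshold()` removes any day (case or referent) whose
own daily PM2.5 exceeds 35 µg/m³, dropping a set entirely when its case
day is removed or no referent remains. The rule is day-level by
construction; a stratum-level alternative (dropping whole months) would
discard compliant person-days for no design reason.

## Segregation indices

From a block-group race-count table (non-Hispanic white and black counts
nested in tracts):

* **RRS** (racial residential segregation score), a
  concentration-at-the-extremes score
  $\mathrm{RRS} = (n_\text{white} - n_\text{black})/n_\text{total} \in [-1, 1]$:
  −1 means an entirely black block group, +1 entirely white, 0 equal
  counts. For categorical analyses the score is binned at
  −0.5, −0.1, 0.1, 0.5 into groups G1–G5, half-open so every score falls
  in exactly one bin; G1 (most black-segregated) is the reference.
* **IRD** (index of racial dissimilarity), the classical dissimilarity
  index of a tract's block groups,
  $D = 50\sum_i |b_i/B - w_i/W| \in [0, 100]$, assigned to every member
  block group. It is 0 when every block group mirrors the tract's racial
  mix and 100 under complete separation. A within-tract (rather than
  single-block-group) formulation is used because it attains the full
  0–100 range.

Undefined scores are flagged and excluded, never zeroed: a
zero-population block group has no RRS; a tract with no black or no
white residents has no IRD.

## Reporting scale

Fitted per-µg/m³ log odds are reported as percent change in mortality
risk per 10 µg/m³: $PC = 100(e^{10\beta} - 1)$, with Wald 95% intervals
transformed the same way (multiplier 1.96; set counts are large enough
that no small-sample correction is warranted). For a continuous modifier
the effect at value $m$ uses $b(m) = \beta_1 + m\beta_2$ with the
delta-method standard error
$\sqrt{v_{11} + m^2 v_{22} + 2m\,v_{12}}$, evaluated at the 10th, 50th
and 90th percentiles of the modifier over decedents (nearest-rank
convention; percentiles are decedent-weighted, not block-group-weighted,
because the effect estimates apply to the analysis population).
Re-centering the modifier and refitting would give identical point
estimates; the delta method is used because it needs no refit. For the
five RRS categories, each non-reference effect combines
$\beta_1 + \beta_{2c}$ with the corresponding 2×2 covariance block, and
one Wald interaction p-value per level is reported against G1.
Interaction p-values for continuous modifiers are single-coefficient
Wald tests; no multiplicity adjustment is applied across modifiers, and
no joint 4-df test is reported for the categorical interaction.

## The synthetic-data generator

Real mortality registries of this kind are confidential, so the package
ships a generator (`simulate_study()`) producing complete study inputs
with known ground truth. What it emulates, and why:

* **Census composition.** Tract-level black population share drawn from
  a three-part mixture — tracts with no black residents, a right-skewed
  low-share bulk, and a small set of high-share tracts spread over their
  component's quantiles so the full RRS range (all five categories) is
  populated at every seed. Block-group shares scatter around their
  tract's share with Beta concentration `kappa_within = 80`, which sets
  within-tract homogeneity and hence the IRD level (median in the
  mid-teens at default). Defaults target decedent-weighted percent-black
  anchors of 0% at the 10th and roughly 16% at the 90th percentile, with
  a median near 2% — a strongly white-majority urbanized region.
* **Exposure.** Daily PM2.5 per cell = annual cycle (amplitude
  2.5 µg/m³, summer peak) + static cell offset + AR(1) deviation
  (ρ = 0.6, innovation sd 4.5, hence day-to-day marginal sd ≈ 5.6) +
  occasional regional episodes (on 1.5% of days, an exponential boost
  with mean 8 µg/m³ shared across cells, mimicking inversion or smoke
  days — these supply the rare exceedances of the 35 µg/m³ standard that
  the restriction analysis filters), truncated at zero. The cell offset includes 0.08 µg/m³ per percentage
  point of neighborhood percent black, so blacker neighborhoods see
  systematically higher PM2.5 — the cross-sectional gradient seen in
  segregated urban areas. Temperature is a shared regional annual cycle
  (amplitude 12 °C) with AR(1) noise.
* **Events.** Daily death counts per block group are Poisson with a
  log-linear rate: baseline `base_rate = 0.056`/day (≈20,000 events over
  the default 500 block groups × 2 years), day-of-week multipliers, a
  U-shaped lag-window temperature response (minimum near 15 °C, so
  winter cold raises risk — most of the seasonal mortality pattern is
  temperature-mediated), a small residual winter amplitude (0.05 on the
  log scale), the exposure term $\beta^* \cdot \mathrm{PM}_{w}$ and
  optionally an interaction $\delta^* \cdot \mathrm{PM}_w \cdot m$.
  Counts are expanded to person-records with race drawn from the block
  group's two-race composition. For rare daily events this Poisson rate
  is likelihood-equivalent to the conditional-logistic target: given the
  stratum total, events distribute multinomially with softmax
  probabilities, so the fitted exposure log odds estimates
  $\beta^* + \delta^* m$ exactly, and pipeline output is directly
  comparable to the echoed truth.

What it does **not** emulate: spatial covariance of PM2.5 beyond the
shared seasonal signal and per-cell offsets; exposure measurement error;
residential mobility; mortality displacement; demographic structure
beyond the two analyzed race groups. Passing recovery tests therefore
show the *estimator and pipeline* are correct under a
correctly-specified rate model — they do not show robustness to exposure
error or model misspecification in real data.

A deliberate design point: the generator's residual (non-temperature)
seasonality is kept small because within-month seasonal trends are
residual confounding that the month-stratified design cannot remove;
with realistic amplitudes this bias is well under 0.1 percentage points
on the per-10 scale, consistent with the design's intended use.

Determinism: the configuration seed fully determines output (census,
exposure and events use seed, seed+1, seed+2 of R's default generator);
identical seeds give bit-identical studies.

## Numerical choices and degenerate inputs

* Newton tolerance 1e-8 on the gradient max-norm; step-halving
  guarantees monotone ascent; the likelihood is concave (tested via
  Hessian eigenvalues), so the optimum is global. The optimizer works in
  a standardized parameterization — columns centered at their overall
  means (a global shift is stratum-constant, hence
  likelihood-invariant) and scaled to unit within-set standard
  deviation — and the convergence norm is measured in those
  standardized units, making the criterion equivariant to covariate
  units. This matters: raw interaction columns (exposure × percent)
  reach values of order 10³, for which an absolute raw-unit 1e-8
  gradient would demand coefficient updates below double-precision
  resolution; for columns of order one the two norms coincide.
  Coefficients and covariance are transformed back exactly.
* Grid-cell ties broken by smallest cell id; distances within 1 µm are
  ties.
* Nearest-rank percentiles: the p-th percentile of n sorted values is
  the value at position ⌈np/100⌉, so reported percentiles are always
  observed values.
* Zero-population block groups, single-race tracts, empty record lists,
  and events whose exposure windows reach before the series start are
  all handled explicitly (flagged exclusion / empty results), never by
  silent substitution.
* Exposure series are validated to be one value per (cell, date) on a
  contiguous daily calendar with PM2.5 ≥ 0.

## Validation scales

The test suite validates the pipeline at the study conditions the
package declares: referent selection against brute-force enumeration
over 1999–2012; the Newton optimum against a dense grid search and
`survival::clogit` (agreement to 1e-6); main-effect recovery over 200
full-scale replicates (truth 2% per 10 µg/m³; mean error under 0.2
percentage points, 95% CI coverage within [92%, 98%]); interaction
type-I error over 400 replicates at a reduced scale (120 block groups,
one year, ≈4,000 events; rejection rate within [3%, 7%]); and
effect-modification recovery over 100 full-scale replicates with truth
rising from 1.6% at percent black = 0 to 3.4% at 16 (per-percentile CI
coverage ≥ 90%).

## Worked example

```{r example, eval = FALSE}
cfg <- cc_sim_config(seed = 1, beta_star = log(1.02) / 10)
study <- simulate_study(cfg)
res <- cc_analysis(study$events, study$census, study$exposure)
percent_change(res$fit$beta[["pm25_window"]],
               res$fit$se[["pm25_window"]])

# effect modification by neighborhood percent black
cfg2 <- cc_sim_config(seed = 1, beta_star = log(1.016) / 10,
                      delta_star = (log(1.034) - log(1.016)) / 160,
                      modifier = "pct_black")
study2 <- simulate_study(cfg2)
res2 <- cc_analysis(study2$events, study2$census, study2$exposure,
                    spec = cc_model_spec("pct_black"))
dec <- res2$design[res2$design$is_case == 1, ]
effect_at_modifier(res2$fit, modifier_percentiles(dec$pct_black))
```

## Known limitations

* The likelihood is the exact conditional logistic one, but inference is
  Wald/asymptotic; exact-conditional inference for tiny strata counts is
  out of scope.
* One exposure series per record (residential address), fixed over the
  study period.
* Continuous modifiers enter interactions linearly; nonlinear effect
  modification would need basis expansion by the user.
* The NAAQS restriction filters on each day's own 24-hour value, not on
  the window mean; window values of retained days may still average in
  an above-threshold previous day.
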