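---
title: "Methods: estimating and forecasting schooling distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and forecasting schooling distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The estimation problem

Surveys and censuses report the distribution of completed years of
schooling for some location–age–sex cells in some years, with three
complications: different data providers carry systematic biases, ages
are often reported in 5-year groups, and coverage over time is sparse
and irregular. The goal is a complete single-year grid of 19-bin
attainment distributions (0–18 years, top-coded) for 1970–2018, a
forecast to 2030, and metrics of progress and inequality, all with
uncertainty.

Two scalar summaries carry the first half of the pipeline: mean years
of schooling divided by 18 and the proportion with zero years, both
modelled on the logit scale. The full distribution is reconstructed at
the end from these two summaries by nearest-neighbour search in the
library of observed distributions. This split works because the two
summaries are the best-identified features of noisy tabulations, while
the library supplies realistic *shapes* conditional on them.

## Assumptions

* **Cohort stability.** After age 25, a birth cohort's attainment
  distribution is fixed; observed within-cohort change across surveys
  is survey artefact plus residual drift (differential mortality,
  migration), which the cohort stage removes or absorbs.
* **Provider bias is a constant logit shift** per provider (regionally)
  and per provider-within-location, not varying by age or sex.
* **Smoothness over time.** Deviations of the truth from the age-period
  prior evolve smoothly over calendar years (Matérn, ν = 2, l = 40).
* **Exchangeability of shapes.** Two populations with similar
  (mean, prop-zero) and nearby age/cohort/location have similar full
  distributions.

# Stage-by-stage notes

## Provider-bias adjustment

One REML mixed model per (region, quantity):
`logit(P) ~ age + sex + location + year + (1|provider) + (1|location:provider)`,
with age as the group-midpoint covariate, sex as a female indicator and
location as categorical fixed effects. Adjustment shifts each point by
`u_gold − u_provider`, plus the nested difference in locations that have
gold-standard data. Standard errors pass through unchanged: the shift is
a known constant on the logit scale and no SE inflation for the
estimated shift is attempted — a deliberate, documented simplification.

Two terms of this model can trade variance freely: when a provider's
bias is constant across locations, the nested BLUPs can represent a pure
provider shift and the optimizer may assign the provider variance to the
nested grouping (leaving `u_provider` at zero). The *applied total*
adjustment is invariant to that re-allocation, so the package reports
provider effects as the provider BLUP plus the location-average of its
nested BLUPs, and centres nested effects within provider. Recovery of
injected biases is tested on that reported quantity.

Identifiability caveat: provider effects are estimated against a linear
year term. If a provider's survey years barely overlap the gold
standard's and the true secular trend is nonlinear, the provider effect
absorbs trend curvature. The synthetic scenario therefore gives all
providers overlapping year coverage — as real census/DHS programmes
have — and the validation harness shows the expected
more-data-is-better behaviour only under such overlap.

## Cohort extrapolation

All pairs of observations of the same (quantity, location, sex, birth
cohort) qualify if at most 10 years apart, both after 1990 and both at
ages ≥ 25. Differences are **annualised** (divided by the year gap) and
indexed by the midpoint age: the input data mix 1–10-year gaps, and
only an annual-rate reading gives the age-spline model a well-defined
domain and makes accumulation telescope exactly (a→b then b→c equals
a→c by construction). The per-pairing bias is the mean annualised
change of cohorts whose midpoint age lies in [60, 70]; subtracting it
centres the pairing's average change at 65 at zero, reconciling the
window definition with the centring target. The aging model is
`y ~ ns(age, knot 70) + (1 | super_region/location)`, REML; projection
accumulates the population-level predicted annual change between
integer ages, adding the residual variance per year crossed to the
point's prediction variance. Backwards projection stops at age 25.

## Age-period prior

Per (sex, region, quantity):
`logit(P″) ~ (year − 1994) + ns(age, knots 45, 65) + (1 | α-group)`.
Year is centred at 1994 (midpoint of 1970–2018) purely for numerical
conditioning. The random-intercept grouping is country × age by default
(the formula's subscript) with a `country` switch (the prose variant);
both are exposed as configuration because either is defensible, and
neither is asserted as "the" choice. Spline knots outside the observed
age range are dropped, and the spline's degrees of freedom are capped
below the number of distinct ages, so desk-scale grids with three age
groups degrade gracefully to a low-order age effect.

## Gaussian process regression

The prior surface is the GP mean function; data are the cohort-filled
points with noise variance σ_p² = (delta-method logit SE)² + accumulated
extrapolation variance. The kernel amplitude σ² is the squared scaled
MAD of prior residuals pooled per super-region × sex — robust because
sparse countries produce heavy-tailed residual pools — with a global
fallback for groups under 10 residuals. The posterior is exact
(Cholesky-free direct solve; a 1e-9 jitter retry guards singular
systems). Draws are antithetic with a seed derived from the master
seed: for even draw counts the draw mean equals the posterior mean to
machine precision, which the tests exploit, and the draw SD is checked
against the analytic posterior SD instead.

With ν = 2 and l = 40 years the correlation at 10 years is still ≈ 0.95:
the smoother resists chasing single surveys and interpolates decades
with data on both sides.

## Ensemble KNN reconstruction

Candidates are ranked by Mahalanobis distance on
(logit(mean/18), logit(prop₀)) with the 2×2 covariance S pooled over the
whole library once per run: a single pooled S keeps the metric
consistent across cells.
Ties are broken by library index. The averaging weights use
min-max-rescaled (to [0.001, 1]) absolute age and birth-cohort
differences — the simplest distances consistent with the rescaling
rule — and the categorical location distance 0.001/0.33/0.66/1. The
P constants are fixed weights and are *not* themselves rescaled.

The candidate library is built from the raw observed distributions,
biases and all, as the original database was: provider bias affects
candidate *shapes* only mildly, while the KNN features are each
candidate's own summaries, so the feature-space match stays internally
consistent.

Per-bin smoothing over time uses `stats::lowess` (locally weighted
*linear* regression, span η, no robustness iterations) rather than
`stats::loess`: it is ~30× faster across the ~10⁵ bin-series a run
smooths, and constant series pass through unchanged, which is the
property the pipeline needs. Negative fitted values are clipped at 0
and each year renormalised.

Each GPR draw is mapped through the ensemble independently
(selection, weighting, smoothing and forecasting per draw), so the
final intervals reflect both data noise and model uncertainty.
`ensemble_reconstruct()` inlines the select–weight–average loop for
speed; a test pins exact equality with the composed exported
operations.

## Forecast

Per bin, the rate of change is the mean annual logit difference over
2004–2018 (equivalently the telescoped endpoint difference divided
by 15; "weighted" average with uniform weights, matching the printed
divisor). Projection applies one logit step per year; since per-bin
logit dynamics cannot preserve the simplex, each year is renormalised
after the back-transform — the minimal repair that keeps the printed
per-bin dynamics to first order. Zero bins are clipped at 1e-6 before the
logit, so empty bins move only through renormalisation. Forecasts
replace cohort-informed estimates from 2019 (ages 25–29), 2024 (30–34)
and 2029 (35–40); the pipeline forecasts the youngest group.

## Metrics

AID is defined over **ordered pairs including self-pairs**,
Σ_j Σ_k p_j p_k |j−k|, which makes the identity AID = 2·mean·Gini hold
exactly with the with-replacement population Gini — the identity is
stated as exact, and the tests verify it against an independent
Lorenz-curve oracle. Gini of a zero-mean distribution is 0 by
convention. The gender-gap level decomposition uses expected years
within bands (0–6, 6–12, 12–18); several decompositions are possible,
and the band reading is chosen because it telescopes exactly to the
total gap; outputs label it as such.
Aggregation (population-weighted bin-wise mean) happens *before* metric
computation, so aggregate AID includes between-member spread. The gap
sign convention is male − female.

# The synthetic world

`make_world()` draws, per country and sex: a logistic growth curve of
cohort mean attainment (asymptote 13–17 years, ~3% lower and 8 years
later for women — a persistent but closing gender gap; midpoint
1950–1985; rate 0.05–0.12 per cohort year), a proportion-zero curve
declining with the mean, and a bulk dispersion (0.6–1.1 on the logit
scale). The distribution is a point mass at zero plus a discretised
logit-normal over 1–18 — deliberately *not* determined by
(mean, prop-zero) alone, so the ensemble stage is exercised
non-trivially. Providers apply logit-scale biases to the two summaries
via an exponential tilt of the bulk (solved by a vectorised Newton
iteration, exact to 1e-12), then 5-year age-group averaging and
multinomial noise at the stated effective sample size. The default
scenario is three providers — a decennial gold-standard census
(n = 10 000, 5-year groups), a DHS-like survey (five-yearly, single
ages, n = 3 000, mean bias −0.12 / prop-zero bias +0.15 logits) and a
MICS-like survey (decennial, 5-year groups, n = 2 000, +0.08 / −0.10) —
over 12 countries in 3 super-regions.

What the generator does **not** emulate: real microdata layouts,
nonresponse and weighting, migration- or mortality-driven cohort drift
(cohorts are exactly stable, so the cohort stage's bias term is tested
against injected artefacts, not against demographic drift), binned
attainment questionnaires needing crosswalks, and the multinomial noise
model is a stand-in — the sources' true error processes are unknown. A
green recovery test therefore establishes that the pipeline inverts the
*stated* degradations (bias, binning, sampling noise, sparsity) around
a smooth truth; it does not certify performance under drift or
non-sampling error.

# Numerical choices

* Proportions are clipped to [1e-4, 1−1e-4] before any logit (the
  data legitimately contain 0 and 1); forecast bins to [1e-6, 1−1e-6].
* Mixed models: lme4 REML; singular fits are accepted silently (they
  are routine in no-noise tests); rank-deficient age terms are avoided
  by construction (knot filtering, df caps).
* GP: 1e-9 jitter retry on singular covariance; posterior variances
  floored at 0 before the square root.
* KNN: partial sort for the K-th distance, then stable ordering with
  ties broken by library index.
* All randomness flows from one master seed through fixed offsets
  (`derive_seed`), kept below 2³¹; reruns are bit-identical.
* Holdout scoring shifts held-out points onto the gold-standard scale
  with the training fits; otherwise provider bias forms an error floor
  that grows with the share of biased test points and masks data-volume
  effects.

# Test budget scaling

The end-to-end acceptance run uses the full default scenario
(12 countries, draws = 100, ≈5 minutes); the holdout-consistency
criterion re-fits the summary stages ten times and therefore uses a
reduced world (6 countries, every-second-year survey ages, draws = 0)
and measures the density doubling from the sparse base (5 → 10 DHS
waves), where the data-volume signal is not saturated. Unit tests use
two-country worlds that run in seconds.

# Limitations

* Desk-scale only: production-scale global estimation needs a
  restricted multi-thousand-source survey database that cannot be
  shipped; the package ships the machinery plus the synthetic harness.
* The bias model identifies provider effects only where provider
  coverage overlaps in time/space with the gold standard.
* The age-period model is linear in year on the logit scale; curvature
  must be absorbed by GPR, so very long gaps revert toward a straight
  line in logit space.
* Ensemble reconstruction cannot produce shapes absent from the
  library, and its two-feature match leaves residual shape error (the
  feature-consistency tolerance in the tests).
* Forecast uncertainty reflects propagated estimation uncertainty, not
  structural uncertainty about future schooling policy.
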