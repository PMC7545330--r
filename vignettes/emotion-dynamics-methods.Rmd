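---
title: "Measuring emotion dynamics across intensive longitudinal methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring emotion dynamics across intensive longitudinal methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emodyn)
```

## The problem

Intensive longitudinal assessment (ILA) designs record a person's
positive affect (PA) and negative affect (NA) repeatedly over days:
ecological momentary assessment (EMA) prompts several in-the-moment
ratings per day; end-of-day (EOD) diaries collect one summary rating per
evening; and the day reconstruction method (DRM) has respondents divide
one day into self-defined episodes and rate each. From any of these
streams one can compute person-level *emotion dynamics* — how much, how
fast, and how jointly a person's feelings move. Whether the three
designs yield interchangeable measures is an empirical question; this
package implements the full measurement battery and the comparability
analysis needed to ask it, plus a calibrated synthetic-study generator
standing in for panel data that cannot be redistributed.

## The measurement battery

All 11 measures are computed identically for every method, from each
person's PA and NA series (episodes enter as midpoint-timestamped
ratings rescaled to 0–100 via `100 (raw + 0.5) / 7`):

* **Mean level** (PA, NA): the person's average rating.
* **Variability** (PA, NA): the within-person sample SD.
* **Instability** (PA, NA): the root mean square successive difference
  (RMSSD) over retained adjacent pairs.
* **Inertia** (PA, NA): the person-specific first-order autoregressive
  slope — an affect rating regressed on the previous retained rating.
* **Network density**: the sum of absolute values of the 2
  autoregressive and 2 cross-lagged person-specific parameters of a
  bivariate lagged model of PA and NA.
* **Mixed emotions**: the MIN index, per time point
  `(PA + NA) − |PA − NA| = 2 min(PA, NA)`, averaged over time.
* **Dialecticism**: the within-person PA–NA correlation (−1 =
  maximal bipolarity).

### Gap rules

Measures that use temporal adjacency (instability, inertia, density)
require roughly equal spacing, so lag pairs are filtered before use:

* **EMA**: pairs spanning two calendar dates (overnight) are dropped, as
  are pairs more than 10 h apart.
* **DRM**: pairs of episode *midpoints* more than 10 h apart are
  dropped.
* **EOD**: only pairs of consecutive calendar days are kept — a skipped
  diary day breaks the chain. The source design states no diary gap
  rule; we impose the consecutive-day restriction because a 48-h
  "successive difference" is not comparable to a 24-h one. Both the 10-h
  cap and this rule are arguments, so either can be relaxed.

"Overnight" is operationalized as a calendar-date change on the local
clock: the simplest faithful reading of an evening-to-morning gap, with
no cross-timezone arithmetic (single-panel designs never compare clocks
across persons).

### Empirical-Bayes estimation of inertia and density

Person-specific lagged slopes estimated by per-person OLS are extremely
noisy at realistic series lengths. Inertia and density therefore come
from two-level random-slope models fitted over all persons jointly
(REML via lme4), and each person's coefficient is the *empirical Bayes*
(EB) estimate: the fixed effect plus the conditional mean of that
person's random effect, i.e. the per-person estimate shrunk toward the
population value in proportion to its unreliability. The full
random-effects covariance is tried first; on a convergence warning the
model is refitted with a diagonal covariance and the fallback is
recorded in the fit object. We rely on lme4's own convergence checks
and optimizer defaults rather than bolting a hand-written tolerance on
top of it; re-implementing the stopping rule would add risk without
adding accuracy.

Lagged predictors are within-person centered by default — for density
this is part of the published construction; for inertia the original
description is silent, and we center for consistency so the slope reads
as autocorrelation rather than as a mean-level artifact
(`center_lag = FALSE` restores the uncentered variant).

The inclusion filter requires at least 4 observations per method per
person, counted after ingest validation and before lag filtering (the
threshold concerns data provided, not pairs surviving the gap rules).

## The synthetic-study generator

No raw panel data are deposited, so `generate_study()` creates studies
whose *structure* matches the design: 90 persons, 7 days, 6 EMA prompts
per day in a 12-h window, one diary per evening, one day (uniform among
days 2–7) of 5–20 self-selected episodes rated 0–6, and daily health
items (general health 1–5, where 5 = excellent; pain and fatigue
0–100).

Each person's affect is one latent bivariate VAR(1) on an hourly grid,

\[ x_t - \mu_i = A_i (x_{t-1} - \mu_i) + \varepsilon_t, \qquad
   \varepsilon_t \sim N(0, Q), \]

with person-random set-points \(\mu_i\) and coefficient matrices
\(A_i\) (redrawn if non-stationary). All three methods sample this one
process, which is what gives cross-method correspondence something real
to measure. A VAR(1) was chosen because every target measure has a
known population value under it — e.g. RMSSD/SD \(=\sqrt{2(1-\phi)}\)
for an AR(1) with coefficient \(\phi\) — enabling parameter-recovery
tests rather than snapshot tests.

Default parameters, chosen once from the study's printed descriptives
and not revisited:

* PA set-points Normal(66, 16): printed mean PA ≈ 66 and an
  intraclass correlation (between-person variance share) near 0.6.
* NA set-points log-Normal(meanlog 2.2, sdlog 0.8): right-skewed with
  mean ≈ 12 and floor effects at 0, as NA ratings show.
* Hourly AR coefficients Normal(0.60, 0.12) for PA and
  Normal(0.55, 0.12) for NA: at the ≈2-h spacing the prompt scheduler
  produces, the implied observed lag-1 dependence is near the printed
  inertia values (≈0.4).
* Small negative cross-lags and an innovation correlation of −0.4,
  matching the printed dialecticism of about −0.35.
* Innovation SDs 9.6 (PA) and 7.5 (NA): stationary within-person SDs
  near the printed variability values (≈11 and ≈9).
* Measurement noise SD 4 for EMA and EOD; episode ratings instead get
  quantization error from inverting the rescale formula
  (round-half-away-from-zero to the 0–6 grid).
* EOD summaries default to the mean of the day's waking-window latent
  values (`day_mean`); a `peak_end` variant (average of the day's
  maximum and final value) exists to study recall bias but is off by
  default, since EMA and EOD means were observed to be nearly
  equivalent.
* Prompt spacings are uniform on \([0.75\,W/n,\ 1.10\,W/n]\) after the
  previous prompt (the published scheduling rule); for a 12-h window
  and 6 prompts this yields spacings in [1.5, 2.2] h. The prose
  description "approximately 1–3 hours" is treated as an approximation
  of this formula.
* Episode counts are truncated Poisson(12) on [5, 20] and durations are
  gamma-distributed with a 15-min floor, renormalized to partition the
  waking window exactly, with boundaries at whole minutes (respondents
  enter clock times).
* Health outcomes are linear in the true person parameters (set-points,
  optionally NA innovation SD) plus daily noise — by default pain and
  fatigue load positively on the NA set-point and negatively on PA, and
  general health the reverse, so association analyses have a known
  truth to recover.

What the generator does *not* emulate: circadian within-day rhythms,
non-random prompt non-compliance (only a uniform completion-probability
knob), slow day-scale affect components, and respondent-specific
episode-selection bias. Consequently a green cross-method test
establishes that the *pipeline* preserves correspondence that exists in
the latent process — not that real methods correspond. One visible
artifact: because the latent process mixes within hours, day means
carry little day-to-day dependence, so synthetic EOD inertia is near
zero, whereas real diary data show positive inertia driven by slow
components the model omits. The qualitative ordering (mean levels
correspond most, lagged measures least) survives this and is the
property the acceptance suite tests.

## Comparison statistics

* **Mean differences**: one-way repeated-measures ANOVA (complete
  cases, sphericity assumed — no correction, matching the published
  df of (2, 178) at n = 90), then Bonferroni-adjusted paired t tests.
* **Correlation differences**: the three cross-method correlations of
  one measure are dependent (same persons), so equality is tested with
  a Wald χ² (df 2) on Fisher-z correlations using the Olkin–Siotani
  asymptotic covariance of correlations sharing variables (a
  Steiger-type delta method). The original analysis used
  structural-equation Wald tests; the delta method is asymptotically
  equivalent and fully specified here, and a percentile bootstrap
  replaces the p value if the contrast covariance is singular.
  Pairwise z tests and Cohen q (difference of Fisher-z values) follow
  up.
* **Networks**: the 11×11 correlation matrix per method
  (pairwise-complete), node strength = sum of absolute off-diagonal
  correlations, display threshold = `critical_r(n, 0.05)` (0.21 at
  n = 90). Strength orderings are compared across methods by rank
  correlation.
* **Health**: each person's 7 daily health scores are averaged; each
  measure × outcome × method correlation is computed, equality across
  methods Wald-tested (33 tests: 11 measures × 3 outcomes), and
  incremental validity assessed by OLS of the outcome on the measure
  controlling for mean PA and mean NA.

Correlations are Pearson by default. The published tables print ρ, but
their 0.21 significance cutoff matches the Pearson critical value at
n = 90, so Pearson is the default and `cor_method = "spearman"` (or the
CLI `--rank` flag) switches everything to ranks. The same source prints
0.28 and 0.35 as cutoffs for P < .01 and P < .001 where the standard
two-sided inversion gives 0.27 and 0.34; we implement the standard
inversion and note the discrepancy rather than reproduce it.

## Numerical choices and degenerate inputs

* Variability needs ≥ 2 points, dialecticism ≥ 3 points and nonzero
  variance in both affects; otherwise the cell is missing (`NA`), never
  silently 0.
* RMSSD over an empty retained-pair set is missing; a constant series
  gives 0.
* Zero-duration episodes get midpoint = start with a warning; zero
  total rating variance makes the ICC an error, while zero
  *within*-person variance returns ICC = 1 directly (the mixed model
  cannot fit that boundary).
* The latent state is never clipped; clipping to [0, 100] happens only
  when observations are sampled, so floor effects are a property of the
  measurement, not the dynamics.
* DRM quantization rounds half away from zero; ties cannot occur off
  the half-grid because the rescale map places scores strictly between
  grid midpoints.
* CSV writers emit floats via `%.17g` and timestamps at second
  precision, so write-then-read reproduces a dataset exactly; the
  generator rounds all event times to whole seconds (episode bounds to
  whole minutes) to make that exactness meaningful.
* EOD diaries completed after midnight are assumed to be labelled with
  the intended day: `day_index` is authoritative for the
  consecutive-day rule.

## Known limitations

Single-item PA and NA only — measures needing multiple items per
valence (granularity, emodiversity) are out of scope by design. The
multilevel engine handles at most two lagged predictors (the bivariate
battery needs no more). Numerical equality with the original
Mplus-based Wald statistics is not claimed, only asymptotic
equivalence. The generator's health model is linear with Gaussian
noise; it exists to give association analyses a recoverable truth, not
to model health realistically.
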