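---
title: "Constructing normative percentile values for the PASE score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing normative percentile values for the PASE score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasenorms)
```

## The problem

The Physical Activity Scale for the Elderly (PASE) is a 7-day-recall
questionnaire whose weighted item sum yields a total activity score from 0
to over 400. A raw score is hard to interpret without a reference: an
85-year-old and a 45-year-old with the same score occupy very different
positions in their age groups. **pasenorms** builds age- and sex-specific
normative percentile curves — the score below which a stated fraction of a
"healthy" reference population falls — from cohort data with survey
weights, and provides the score-to-percentile lookup that makes individual
scores interpretable.

Access to large aging-cohort data is typically restricted, so the package
also ships a synthetic-cohort generator whose ground-truth centiles are
available in closed form. Every stage of the pipeline is tested against
that ground truth; nothing in the package requires restricted data.

## Instrument scoring

The PASE total is

\[
\text{total} \;=\; \sum_{\text{leisure}} w_a \cdot \bar h_a
\;+\; \sum_{\text{household}} w_a \cdot \mathbf 1\{\text{yes}\}
\;+\; w_{\text{work}} \cdot \frac{\text{hours/week}}{7}
\cdot \mathbf 1\{\text{standing or walking}\},
\]

where \(\bar h_a = (\text{freq midpoint days}/7) \times \text{duration
midpoint hours}\) is the average daily time in leisure activity \(a\).
The activity weights and category midpoints are *configuration*, not code:
they ship as a versioned YAML file
(`inst/extdata/pase_scoring_default.yaml`, values from the PASE
administration manual) so the scoring engine is testable under any weight
set. Sitting/sedentary items are parsed but never contribute to the
total. A missing item response makes the whole score undefined by default
(`missing = "undefined"`); an imputation-free partial-score mode exists but
is off by default, because the reference analysis excluded incomplete
questionnaires rather than imputing them.

## The reference ("healthy") sample

Normative values describe a population free of activity restrictions, so
subjects reporting gait-aid use or assistance with any ADL/IADL activity
are excluded, and records with missing eligibility flags or missing PASE
data are dropped rather than guessed: `apply_exclusions()` returns three
disjoint partitions whose sizes always sum to the input. The validity of
the exclusion is checked descriptively (`weighted_descriptives()`, with
inflation weights) and inferentially (`compare_included_excluded()`,
Welch t-tests within 10-year age bands — Welch rather than pooled-variance
because the two groups differ in spread; a `var_equal` toggle restores the
classical test).

## Centile models

### Distributional (GAMLSS-style) regression

Scores at age \(t\) are modelled by a four-parameter family
\(f(y;\mu(t),\sigma(t),\nu(t),\tau(t))\) — location, scale, skewness,
kurtosis — with each parameter curve a linear combination of an age basis
on its link scale (identity for \(\mu\); log for \(\sigma\) and \(\tau\);
identity or log for \(\nu\) depending on the family's domain). Ten
families are implemented: the sinh-arcsinh variants SHASH, SHASHo,
SHASHo2; skew exponential power types SEP1, SEP2, SEP4; Johnson's SU (JSU,
JSUo); and skew-t types ST1, ST5. Each density is transcribed from its
standard published form and documented in `R/distributions.R`; the
sinh-arcsinh variants nest the normal distribution exactly, which the test
suite asserts to 1e-10.

Fitting maximizes the analytic-weight-weighted log-likelihood
\(\sum_i w_i \log f(y_i;\theta(t_i))\) directly over the basis
coefficients: cyclic block ascent (one quasi-Newton update per parameter
block) plus a joint BFGS polish per outer iteration. Each step can only
increase the likelihood, so the deviance trace is non-increasing — the
fitter's contract, asserted in tests. Convergence is declared when the
relative deviance change falls below 1e-6 (at most 200 outer iterations).
Default smoothers put cubic regression splines (df 3) on \(\mu\) and
\(\sigma\) and constants on \(\nu\) and \(\tau\): the shape parameters are
weakly identified locally, and letting them drift with age mostly buys
variance. All four smoothers are configurable, and parameters can be
pinned (`fit_controls(fixed = ...)`), which is also how the normal-limit
submodel used in tests is obtained.

Because the bases are unpenalized regression splines of fixed dimension,
the smoother "hat" trace equals the coefficient count, so the effective
degrees of freedom for GAIC, \(-2\hat\ell + k\,\mathrm{df}\), is the
number of free coefficients. Candidate families are ranked by GAIC
(`rank_families()`, penalties \(k = 2, 3.84, 5, 9\) all recorded on every
fit), ties within `tie_tol` broken by smaller df, then candidate order.

The families are supported on the whole real line while PASE scores are
non-negative; models are fitted on raw scores and reported centiles are
floored at 0, which only affects extreme low centiles at high ages (the
generator keeps the true sub-zero mass below about 1%).

### Quantile regression

The second approach fits each percentile separately by minimizing the
weighted pinball loss \(\sum_i w_i \rho_\tau(y_i - f(t_i))\),
\(\rho_\tau(u) = u(\tau - \mathbf 1\{u<0\})\), over four basis families:
linear, raw polynomials of order 2-4, a smoothed additive fit, and
fractional polynomials (degree at most 2, powers from
\(\{-2,-1,-0.5,0,0.5,1,2,3\}\), with the usual conventions: power 0 is
\(\log\) age, a repeated power multiplies by \(\log\) age; ages are scaled
by 10 for conditioning). The solver is the Hunter-Lange
majorize-minimize iteration — each step a weighted least-squares solve
from an \(\varepsilon\)-smoothed \(|u|\), with \(\varepsilon\) driven from
1e-3 down to 1e-11 — followed by a vertex polish: an optimum of a
\(p\)-coefficient quantile regression interpolates \(p\) observations, so
candidates through the smallest-residual points are enumerated and the
best exact loss kept. On every small instance the tests compare against
exhaustive enumeration; intercept-only fits bypass the iteration entirely
and return the exact weighted sample quantile.

The smoothed additive variant parameterizes the fitted values at the
distinct-age nodes (capped at 201 equally spaced nodes) and penalizes the
total variation of the curve's derivative — the sum of absolute
slope changes. The penalty limit is handled exactly: the straight line is
always evaluated as a candidate under the true objective, so
penalty \(\to \infty\) recovers the linear pinball fit rather than an
ill-conditioned iterate. Weighted observations are supported throughout;
whether the reference analysis weighted its quantile models is not
documented, so weighting defaults to on with a flag to disable.

Separately fitted quantile curves can cross. Crossings are removed by
monotone rearrangement (`rearrange_noncrossing()`): values are sorted
across percentile levels at every grid age, which never increases the
total pinball loss and leaves already-monotone curves untouched. This
post-hoc remedy was chosen over jointly constrained multi-quantile
estimation for simplicity; the tables enforce monotonicity either way.

## Model comparison by cross-validation

`stratified_split()` draws 70% of every year-of-age stratum into training
(round half up; single-record strata are flagged and sent whole to
training), `holdout_coverage()` measures the weighted fraction of holdout
subjects below the fitted 5th and 50th centiles and above the 95th, and
`cross_validate()` repeats split-fit-evaluate under sub-seeds derived
reproducibly from one master seed, refitting everything within each
repetition. The reference procedure's selection emphasis on the 5th
percentile is operationalized as a lexicographic rule in
`select_model()`: minimize \(|\bar c_{P5} - 0.05|\); ties within 0.002 are
broken by \(|\bar c_{P50} - 0.50|\), then \(|\bar c_{P95} - 0.05|\), then
fewer failed repetitions. The 0.002 window is roughly one Monte-Carlo
standard error of a coverage mean at the stratum sizes involved, so the
tie-break engages exactly when the P5 criterion cannot distinguish
models.

## The synthetic cohort

`generator_spec()` encodes the study conditions: 51,338 subjects before
filtering, ages uniform on 45-85, 47% female, interview dates spread over
a calendar year, independent inflation and analytic weights (gamma, mean
1), a 22.6% excluded subpopulation (gait aid and/or ADL-IADL flags) whose
scores sit 45 points lower, and missing eligibility flags or missing PASE
data on about 5.9% of the cohort. Included scores are drawn from
SHASHo2 for males and SEP4 for females, with location falling 2.5
points/year (the true median declines by roughly 100 points from 45 to
85), scale narrowing log-linearly with age (75 to 48 for males, 70 to 42
for females), and shape constants chosen so that spread is heavier below
the median than above it and male curves dominate female curves at every
age and percentile — the qualitative structure of the reference
population. The location intercepts are not magic numbers: they are
solved by quadrature at construction time so the included population's
expected score matches the descriptive anchors of 172.57 (males) and
147.39 (females). Scores are censored at zero, so the generator's true
centile is \(\max(0, Q_{\text{family}}(p;\theta(t)))\) — closed form, and
the hook (`true_centile()`) every downstream calibration test uses.

What the generator does *not* emulate: the two-frame survey design and
geographic sampling of a real national cohort, item-level response
behaviour (it draws totals directly), seasonal effects on activity
(deliberately absent, so season-stratified output can be checked against a
known null), and real-data features such as digit preference, score
heaping, or informative missingness. Passing tests therefore demonstrate
that the machinery recovers known truth under clean conditions, not that
any particular family fits real PASE data.

## Numerical choices

* Quantile functions use closed forms where the family admits one;
  otherwise monotone bracketed root finding on the CDF (vectorized
  safeguarded bisection for SHASH; `uniroot` to ~1e-10 over an adaptive
  quadrature CDF for SEP1/SEP2/ST1). Sampling never approximates: closed
  inverse-CDF where available, exact selection/reflection representations
  for the Azzalini-type families.
* Densities are computed in log space; \(\sigma\) and \(\tau\) are fitted
  on the log scale so the optimizer works on unconstrained coordinates.
  Out-of-domain proposals during fitting are rejected with a large
  objective value rather than an error.
* Initialization: weighted least squares for the \(\mu\) coefficients,
  log residual spread for \(\sigma\), the family's symmetry point for
  \(\nu, \tau\).
* Serialized models are JSON with 17 significant digits — an exact
  IEEE-754 round trip — so a table rebuilt from a stored model is
  bit-identical to one from the in-memory fit (asserted in tests).
  Display tables round to integers; machine-readable CSVs keep full
  precision.
* All randomness flows from one master seed; per-repetition and per-stage
  seeds are derived as \((\text{seed} + 7919k) \bmod (2^{31}-1)\) and
  recorded in the pipeline manifest together with a config hash and MD5
  checksums of every artifact.

## Problem sizes used by the test suite

The packaged tests exercise: distribution internals at 100,000 samples
per family; constant-parameter recovery at n = 10,000 against a direct
maximum-likelihood oracle; age-varying median recovery at n = 20,000
(fitted-vs-true P50 RMSE under 5% of the marginal SD); coverage
calibration at n = 20,000 with 20 cross-validation repetitions; model
selection against a misspecified two-parameter Gaussian competitor in 20
seeded trials at n = 4,000 with 3 repetitions each; and a full pipeline
run at the default cohort size with 3 cross-validation repetitions.
These sizes are the package's own choices for routine verification; the
pipeline defaults (`cv_reps = 100`) remain the reference procedure's.

## Known limitations

* Per-season norm tables refit the selected model on season strata
  independently. At the default cohort size each sex-by-season stratum
  holds roughly 4,500 records, so independently refitted tables vary by
  several score points at the grid edges purely from sampling noise —
  mid-grid cells agree to a point or two, matching the seasonal behaviour
  the method is meant to exhibit, but cell-level agreement much tighter
  than that is not statistically attainable at this scale.
* Effective df equals coefficient count because the spline bases are
  unpenalized; if penalized smoothers were added, GAIC would need the
  hat-trace definition instead.
* The score floor at 0 is a reporting convention; the fitted families
  remain unbounded below, so model-based lookups of scores of exactly 0
  at high ages sit at whatever small percentile the family assigns.
* Only the ten families appearing in the reference analysis's top-five
  lists are implemented; the registry is open to extension but does not
  enumerate the wider screening set.
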