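---
title: "Weighted norming: raking, rank-based INT, and continuous norm models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted norming: raking, rank-based INT, and continuous norm models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rakenorm)
```

## The problem

Norm-referenced tests report an individual's standing relative to a
reference population. The norms are estimated from a normative sample,
which should match the population's composition on the stratification
variables (SVs) that correlate with the measured ability — sex, migration
background, parental education, region. When it does not, the estimated
raw-score distribution is distorted and the norms are biased, either
globally or in specific percentile ranges.

`rakenorm` implements post-stratification by **raking** (iterative
proportional fitting) combined with **weighted rank-based norming** and a
**continuous regression-based norm model**. This vignette documents the
statistical procedures, the tunable parameters, the numerical choices,
and what the accompanying synthetic-data generator does and does not
demonstrate.

## Raking

Let `p_vl` be the population proportion of level `l` of SV `v`, and let
`q_vl(w)` be the corresponding weighted sample proportion under case
weights `w` (initially all 1). One raking step for variable `v`
multiplies the weight of every case in level `l` by `p_vl / q_vl(w)`;
afterwards the weighted marginals of `v` match the population exactly.
Because the step for one variable disturbs the marginals of the others,
the steps are cycled over all SVs until the largest absolute marginal
deviation falls below a tolerance.

Design choices, where the procedure itself leaves room:

* **Convergence criterion.** Maximum absolute marginal deviation
  `< tol`, default `1e-6`, checked after each full cycle; `max_iter = 50`
  cycles (convergence is typically reached within a handful of cycles;
  the count grows with the number of SVs and levels). Non-convergence is
  reported as a flag, not an error.
* **Adjustment order.** The fixed point of the iteration does not depend
  on the order in which variables are adjusted (all targeted levels being
  populated), but intermediate weights do; the order used is therefore
  recorded in the `raking_report`.
* **Standardization.** Weights are divided by their minimum, so every
  standardized weight is `>= 1` and can be read as "how many cases this
  case counts for". Ratios between weights — the only thing that matters
  downstream — are unchanged.
* **Degenerate inputs.** A sample level missing from the targets is an
  error naming the level; a targeted level with no sample weight is an
  error advising to collapse sparse levels (a weight for it would be
  infinite). Cases with a missing SV value are rejected rather than
  silently imputed, since imputation would bias the margins being
  corrected.

Raking uses only the marginal proportions of each SV. Joint population
probabilities are not used; if they must be honoured, the SV combinations
can be recoded into a single variable before raking. Diagnostics:
`check_representativeness()` tabulates signed deviations per level, and
`effective_sample_size()` (Kish, `(Σw)²/Σw²`) quantifies the precision
loss caused by variable weights. As a plausibility rule,
`validate_norm_sample()` warns when a stratum share falls below 5% or an
age group below 100 cases — conditions under which weighting tends to do
more harm than good and levels should be collapsed or more data
collected.

## Weighted conventional norming

Within each (age) group, raw scores are ranked with weights: a case with
raw score `v` gets rank `S + (T + 1)/2`, where `S` is the summed weight
of cases scoring below `v` and `T` the summed weight of the ties at `v`.
With unit weights this is the ordinary midrank; integer weights behave
exactly like replicated cases. Ranks become percentiles through a
rank-based estimator with total weight `W`:

| method          | formula              |
|-----------------|----------------------|
| Rankit (default)| `(r - 1/2) / W`      |
| Blom            | `(r - 3/8) / (W + 1/4)` |
| Tukey           | `(r - 1/3) / (W + 1/3)` |
| van der Waerden | `r / (W + 1)`        |

and percentiles become norm scores by the inverse normal transformation
`m + s Φ⁻¹(p)` on the chosen scale (T = (50, 10) by default; z, IQ, or
any `c(mean, sd)`).

Choices to be aware of:

* **The total `W`.** By default `W` is the summed weight of the group,
  consistent with replacing case counts by summed weights everywhere.
  Standardized weights inflate `W` relative to the case count, which
  perturbs the percentile formulas only through the small offset `c`;
  `total = "count"` uses the raw case count instead.
* **Clamping.** Percentiles are clamped to `(1e-10, 1 - 1e-10)` so
  extreme ranks cannot produce infinite norm scores.
* **Groups.** `age_to_group()` segments a continuous age variable into
  equal-width groups (left-closed intervals, the last one closed) and
  labels them with numeric midpoints, so the group labels can serve
  directly as the explanatory variable of the continuous model. A group
  containing a single distinct raw score yields degenerate norms: it is
  normed with a warning and excluded from the regression.

## The continuous norm model

Conventional per-group norms are noisy and jump at group boundaries.
The continuous model regresses the raw score on powers and interactions
of the person location `l` (the manifest norm score, on the reporting
scale) and age `a`:

    raw ~ intercept + Σ c_ij l^i a^j,   1 <= i+j,  i <= k,  j <= t

Defaults `k = 5`, `t = 3` give 23 candidate terms; reduce them when the
model overfits (wavy percentile curves) or the age trend is weak.

* **Best-subset search.** For every model size the RSS-optimal term
  subset (intercept always included) is found by exhaustive enumeration
  over the weighted cross-product matrix, implemented in compiled code;
  the result is exact, not greedy. Candidate columns are rescaled to unit
  weighted norm before solving — numerically essential once terms like
  `l^5 a^3` appear — and coefficients are rescaled back, which leaves
  every subset's RSS unchanged. Rank-deficient subsets are skipped with
  a warning.
* **Fit indices.** Weighted R² and adjusted R², Mallows
  `Cp = RSS_s/σ̂²_full − W + 2(s+1)` (with `σ̂²_full` from the full
  candidate design; the full model has `Cp = s + 1` identically) and
  `BIC = W ln(RSS_s/W) + (s+1) ln W`, all with `W = Σw` in place of the
  case count. The "number of terms" `s` counts non-intercept terms.
* **Selection.** The smallest model with `R² > .99` (configurable); when
  raking weights are supplied they are used both in the ranking and as
  regression weights. A fixed number of terms (`terms =`) overrides the
  threshold — useful for controlled comparisons and for re-fitting after
  a consistency failure. Since R² is non-decreasing in model size, sizes
  are searched incrementally and the search stops at the first size above
  the threshold; this yields the same selection as fitting all sizes.
* **Consistency.** A valid model must predict strictly increasing raw
  scores in `l` at every age — equivalently, percentile curves must not
  intersect. `check_consistency()` scans an age × norm grid (defaults:
  50 ages over the fitted range; T 25–75 in steps of 0.5, i.e. roughly
  the PR 0.6–99.4 band) and reports every violating interval; increments
  down to `-1e-8` are tolerated as round-off. The clean report carries
  the exact message "No violations of model consistency found."

## Prediction, tables, and curves

`predict_raw()` evaluates the model polynomial; `predict_norm()` inverts
it at a fixed age by bisection to `1e-8`, after verifying monotonicity on
the search interval (default: scale mean ± 5 SD, so that degenerate
reference models such as the identity model remain invertible over their
whole raw range; for polynomial models fitted to real data a narrower
interval such as T 20–80 is often appropriate, since polynomials
eventually turn non-monotone far outside the data). Raw scores outside
the attainable range at an age are clamped to the boundary norm and
flagged, mirroring the finite ranges of printed norm tables.
`norm_table()` tabulates raw → (norm, percentile) at a given age — each
integer raw score maps to the norm of its exact value, without a
continuity correction — and flags tables requested outside the fitted
age range as extrapolated rather than refusing them. By default
`percentile_curves()` exports the PR 2.5 / 10 / 25 / 50 / 75 / 90 / 97.5
band in long format.

## The synthetic-data generator

`population_spec()` describes a population with known ground truth: a
generating norm model, strata with population proportions and mean
performance shifts (in scale SD units), an age distribution, and a
raw-score noise SD. `generate_population()` draws cases (age → stratum →
true location → raw score, rounded and clipped); `biased_sample()`
under-includes designated strata, emulating recruitment bias.

The defaults emulate a receptive-vocabulary normative study: ages
2.6–17.0 (uniform), 15 age groups of 11.5 months, raw-score bounds
0–228, sex 51/49 without a performance difference, migration 70/30 with
a −0.5 SD disadvantage for non-native speakers, and residual noise of 2
raw points. The generating model is the four-term form
`a + la + l²a² + l³a³` that continuous norming typically selects for
such scales, with coefficients

    raw = 28.32 + 3.797 a + 0.05 la + 2·10⁻⁵ l²a² − 1.6·10⁻⁸ l³a³

chosen so that (i) the model is strictly increasing in `l` over T 20–80
at all ages in range (minimum slope ≈ 0.13 raw points per T point),
(ii) the median curve rises concavely from raw 45 to raw 140 with a mild
ceiling from the negative cubic term, (iii) the between-person spread
grows with age, as it does in vocabulary development, and (iv) age trend
and individual differences contribute variance on the same order, so
that every generating term matters and the model family is genuinely
identifiable from a sample of a few thousand cases. All draws are
governed by a single seed; the same seed reproduces a data set exactly.

### What the validation experiments show — and what they do not

Two experiments, re-run by `scripts/acceptance.R`, summarise the
pipeline's behaviour (problem sizes are the package's own choices,
balancing stability of the estimates against run time):

* **Recovery.** A representative sample (n = 4500, 15 groups, noise SD
  2) from a performance-homogeneous population is normed with defaults;
  the fitted model's raw scores at T 30–70 across the age range are
  compared with the generating model's. Homogeneity matters here: with
  shifted strata the population location distribution is a mixture, and
  manifest norm scores then target the mixture quantiles, not the
  generating scale's — the comparison would conflate the two. Typical
  recovery RMSE is ≈ 1.1–1.2 raw points, below the noise SD.
* **Weighting benefit.** Over 20 replications, a population of 30,000 is
  sampled (n = 4500) with the shifted stratum under-included 2:1, and the
  median curve is estimated twice from the same sample: unweighted, and
  weighted by raking back to the population marginals. The error
  reference is the population median curve, i.e. the raw curve at the
  stratum-mixture median location (≈ T 48.5) — raking recovers the
  population distribution, so that is the estimand. Both arms use a
  fixed four-term model so that the paired comparison isolates the
  weighting effect from model-selection variability. The raked-weighted
  mean RMSE is consistently below the unweighted one (≈ 0.22 vs ≈ 0.33
  raw points).

The generator draws i.i.d. cases with Gaussian locations and additive
Gaussian noise. Real normative data deviate from this in ways the
simulations do not probe: clustered recruitment (schools), floor and
ceiling effects beyond a mild polynomial ceiling, item-level effects,
non-Gaussian ability distributions, and measurement error that varies
with ability. Passing these experiments therefore demonstrates the
correctness of the weighting and norming machinery under controlled
conditions, not the adequacy of any particular norm model for real data
— model fit, the consistency report, and percentile plots must be judged
per application.

## Limitations

* Raking corrects marginal composition only; it cannot repair severe
  under-representation (high weights inflate variance — watch the Kish
  effective sample size) and cannot compensate for strata that are
  missing entirely.
* Weights enter the regression as precision weights; whether sampling
  weights belong in a regression at all is debated, but for norming the
  weighted fit avoids over-fitting regions that are merely over-sampled.
* Polynomial models extrapolate poorly: tables outside the fitted age
  range are flagged, and inversion is restricted to an explicitly
  monotone norm interval.
* Cross-validated model selection and confidence intervals for norm
  scores are out of scope; selection is by the R² threshold and the fit
  indices reported with every model sequence.
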