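---
title: "Assessing and adjusting survey-based perinatal mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and adjusting survey-based perinatal mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(perimort)
```

## The measurement problem

In most low- and middle-income countries, household surveys with a
reproductive calendar and a birth history are the main population-level
source of data on stillbirths and neonatal deaths. Three reporting problems
limit those data:

* **Omission** — a death, most often a stillbirth, is simply not reported.
* **Transference** — misclassification between stillbirths and very early
  neonatal deaths (days 0–1) in either direction; a newborn who is alive but
  not breathing may be reported as a stillbirth, and vice versa.
* **Heaping** — the reported age at neonatal death is rounded onto day 7,
  which pushes deaths out of the perinatal window (days 0–6).

`perimort` implements an integrated workflow: restructure per-pregnancy
records into an interval-censored cohort, compute four quality indicators
with reference plausibility bands, and fit a family of adjustment models
built on a modified Gompertz–Makeham hazard.

## Data model and cohort construction

The analysis window runs from 7 months' gestation (the survey proxy for the
28-week stillbirth definition) through the end of day 9 of life, split into
10 intervals: the stillbirth interval `STB`, the pooled days 0–1 interval
`D0-1`, and single days 2–9. Days 0 and 1 are always pooled because surveys
are inconsistent about whether "day 0" means the first 24 hours or the
calendar day of birth. Days 7–9 lie outside the perinatal window; they are
retained only so the day-7 heaping index can be computed, and follow-up is
censored at day 10.

Eligibility mirrors standard survey practice: pregnancies terminated before
7 months are excluded, conceptions must fall 7–66 months before the
interview, ongoing pregnancies of at least 7 months enter as censored in the
stillbirth interval, and livebirths in the interview month are assumed to
have survived the first week. Intervals are half-open in age — day *k* is
[k, k+1) — and deaths reported at 10 or more days are censored at day 10
(they survived the analysis window).

Sampling weights enter as frequency weights on all counts. Whether published
survey life tables are weighted is not always stated, so both modes are
supported (`use_weights`); with unit weights they coincide.

```{r}
sim <- simulate_cohort(cohort_params(n_pregnancies = 5000), seed = 1)
counts <- build_interval_counts(sim$records)
counts
```

Because censoring here occurs only at interval boundaries, the life-table
conditional risk is `q_j = d_j / n_j`. An actuarial half-interval correction
(`q_j = d_j / (n_j - c_j/2)`) is available behind the `interior_censoring`
flag for data where censoring can fall inside intervals, but is off by
default since the cohort design produces none.

## Quality indicators and plausibility bands

Four indicators, each compared against fixed reference bands derived from
vital registration, historical, and prospective pregnancy-outcome data:

| Indicator | Plausible range | Flags |
|---|---|---|
| Heaping index: `5 * d(day 7) / sum d(days 5-9)` | 0.8–1.3 | misreported age at death |
| Stillbirths / deaths days 0–1 | 1.7–3.0 | stillbirth omission or transference |
| Stillbirths / deaths days 0–6 | 1.0–1.9 | stillbirth omission or transference |
| Deaths days 0–1 / days 2–6 | ≥ 2.4 | under-reporting of very early deaths |

Band edges are printed with touching endpoints in reference tables; we
resolve them as lower-inclusive, upper-exclusive intervals so that every
nonnegative value maps to exactly one band. The D0–1/D2–6 indicator has only
a one-sided rule: values below 2.4 are labelled "under-reported" rather than
being forced into the three-band scheme. An indicator is undefined exactly
when its denominator is zero; undefined values classify as "unclassifiable"
and never fire an adjustment trigger.

Two fixed constants of the method drive the adjustments (both configurable
but not re-estimated from the data, since they come from a reference corpus):
the stillbirth constraint fires when stillbirths/D0–1 < **1.89**, and D0–1
weighting fires when D0–1/D2–6 < **2.4**.

## The four models

Writing `q_j` for the conditional risk in interval `j`, all models act on the
complementary log-log scale, `cloglog(q_j) = log(-log(1 - q_j))`, where the
interval model is equivalent to a piecewise-exponential hazard.

**Model 1 (observed).** One coefficient per interval,
`cloglog(q_j) = gamma_j`. The saturated binomial likelihood separates over
intervals, so the MLE is the closed-form life table `q_j = d_j / n_j`; the
package computes it that way and the tests verify the equivalence against an
independent cloglog GLM fit.

**Smooth tail (all Gompertz–Makeham models).** For days 2–9 the hazard is
`h_j = gamma_0 + exp(alpha + beta * x_j)` on the day midpoints
`x = 2.5 .. 9.5`: a nonnegative Makeham floor plus a log-linear Gompertz
decline, three parameters for eight intervals. Because the reference model
family is stated recursively for these intervals, this concrete smooth form
is an interpretation — documented here prominently — chosen to fulfil the
stated role of the linear predictor: it cannot reproduce a spike at day 7,
so fitting it redistributes the heap across neighbouring days. The fitted
heaping index (from expected deaths on days 5–9) lands in the plausible band
0.8–1.3 for heaped inputs.

Numerically, the Makeham floor trades off against the Gompertz term along a
flat likelihood ridge, so the fit profiles the likelihood over a
deterministic `gamma_0` grid with inner two-parameter fits (log-linear
regression starts) and polishes the best point with a bounded quasi-Newton
run; `gamma_0 >= 0` is enforced by the bound, `beta` is unconstrained
(typically negative). Intervals with zero deaths get a `q = 0` sentinel
(`gamma = -Inf`) rather than a penalized estimate, preserving exact
life-table equivalence in the saturated model.

**Model 2 (stillbirth constraint).** When the stillbirth trigger fires, the
constraint `gamma_1 = gamma_2 + log(1.89)` is enforced exactly by
substitution — the fitted stillbirth-to-D0–1 *hazard ratio*
`exp(gamma_1 - gamma_2)` equals 1.89 by construction, independent of the
optimizer path. A design choice deserves emphasis: with the constraint
active, the observed stillbirth count is excluded from the likelihood and
`gamma_2` is estimated from the neonatal data alone. The observed stillbirth
count is precisely the quantity the adjustment deems unreliable; retaining
it in a joint likelihood would pull the adjusted stillbirth rate most of the
way back toward the biased observed value (the stillbirth interval has the
largest at-risk set, so it would dominate), defeating the adjustment and
making omitted stillbirths unrecoverable in principle. Anchoring on the
D0–1 hazard reproduces the reference rule "set stillbirths/D0–1 to 1.89"
and leaves the early neonatal rate essentially unchanged under model 2. The
reported log-likelihood is still evaluated over the full table at the
fitted parameters, so the unconstrained fit always dominates the
constrained one on the same table. When the trigger does not fire the
constraint is skipped and recorded.

**Model 3 (D0–1 weighting).** When the weighting trigger fires, D0–1 deaths
are multiplied by `2.4 / r` (with `r` the observed D0–1/D2–6 ratio), so the
weighted table attains the reference ratio exactly. Flow conservation is
preserved by shrinking later entrants — the extra deaths come out of the
day-10 survivors; the alternative of inflating the cohort so downstream
intervals are untouched sits behind `balance = "inflate-cohort"`. Weighting
touches only neonatal intervals, so the model-3 stillbirth rate always
equals model 1's. If D0–1 deaths are zero the weight is undefined and the
table is flagged degenerate; if days 2–6 have no deaths the operation
errors.

**Model 4 (both).** The table is weighted first, the stillbirth trigger is
re-evaluated on the weighted table (the inflated D0–1 count may already
imply enough stillbirths), and the constraint applied if it still fires.
This sequential reading of "adjust for both simultaneously" avoids
over-adjusting stillbirths that the weighting has already implied; it is a
documented choice where the wording is ambiguous. When both triggers fire,
`sbr_4 >= sbr_2 >= sbr_1` and `enmr_3 >= enmr_1`.

Rates come from the fitted life table: stillbirth rate `1000 * q_1` per 1000
births, early neonatal mortality `1000 * (1 - prod(1 - q_j), j in days 0-6)`
per 1000 livebirths, perinatal mortality combining both per 1000 births.
Printed output rounds to one decimal; full precision is retained internally.
Relative differences are always per-survey, `100 * (rate_m - rate_1) /
rate_1`, and multi-survey summaries report the *median of per-survey
differences*, not the difference of medians.

```{r}
adj <- adjust_survey(counts)
adj
```

## The synthetic generator and what it does (not) show

`simulate_cohort()` draws each pregnancy independently: ongoing with a fixed
probability, else stillbirth, else a livebirth walked through the daily
risks. Its defaults are fixed study conditions, chosen once:

* cohort size 10,000 pregnancies — a realistic single-survey size (survey
  cohorts of this kind average roughly 13,000 pregnancies);
* true stillbirth risk 0.025 (25 per 1000 births, a higher-mortality
  setting);
* daily risks from `ratio_consistent_hazards()`: the D0–1 risk and a
  geometrically declining day profile (ratio 0.7) calibrated so the *true*
  expected-count ratios sit exactly at the reference constants,
  stillbirths/D0–1 = 1.89 and D0–1/D2–6 = 2.4. This is the regime in which
  the adjustment constants are correct, i.e. the estimand the method aims
  at. True rates: 25.0, 19.2, and 43.7 per 1000;
* ongoing fraction 0.03 — roughly the share of a 60-month conception window
  still pregnant at ≥ 7 months at interview;
* day-0 share of pooled D0–1 deaths 0.5 (reported day only; prospective
  studies place it anywhere between 21% and 81%, which is why the interval
  is pooled).

`inject_reporting_errors()` applies the error taxonomy with one multinomial
draw per record over keep/omit/relabel (mutually exclusive, avoiding
ill-defined compositions) plus independent heaping draws for deaths on days
5, 6, 8, 9. Three presets key the corruption load to the plausibility bands;
`"probable"` (stillbirth omission 0.25, transference 0.03 each way, D0–1
omission 0.15, heaping 0.3 per source day) reproduces the indicator profile
typical of most surveys, including a heaping index near 2.

What the generator does *not* emulate: month-by-month calendar strings,
correlated reporting within interviewer or cluster, covariate-dependent
error rates, multiple births' within-pair correlation, and sampling-design
weights beyond i.i.d. draws. Passing recovery tests therefore shows that the
models invert the error taxonomy they target under independence — not that
real-survey biases of other shapes are corrected.

## Recovery experiment

`recovery_experiment()` runs simulate → corrupt → adjust over seeded
replicates and compares each model with the *analytic* truth (rates implied
by the parameters, not the sample — recovery is measured against the
estimand; sample-based truth sits behind a flag). Under the default
conditions (200 replicates of 10,000 pregnancies, "probable" corruption):
model 1 understates the stillbirth rate by about a quarter — by
construction, since omitted stillbirths are simply missing — while model 4
is unbiased to within a few percent and beats model 1 on absolute perinatal
error in well over 90% of replicates. The replicate count of 200 and cohort
size of 10,000 are the package's fixed experiment conditions; they keep the
full experiment under a minute on one core.

```{r, eval = FALSE}
rec <- recovery_experiment(n_reps = 200, seed = 1)
rec
```

## Numerical and degenerate-input choices

* Optimizer convergence: relative log-likelihood change below `tol`
  (default 1e-8) within the L-BFGS-B bounds; non-convergence after the
  profile-and-polish sweep is an error carrying the likelihood trace.
* Zero-death intervals: `q = 0` sentinels, flagged, never penalized.
* Zero denominators: indicators undefined, triggers off, classification
  "unclassifiable"; the D0–1 weight is undefined (degenerate flag) when
  D0–1 deaths are zero, an error when days 2–6 are empty.
* Band boundaries: lower-inclusive, upper-exclusive, so a ratio exactly at
  2.4 is plausible and does not trigger weighting; the trigger rules are
  strict inequalities.
* Quantiles in multi-survey summaries: the median-unbiased definition
  (`type = 8`), fixed and documented since reference reports rarely state
  their quantile rule.
* Per-model failures in `adjust_survey()` are captured per model; the other
  models' outputs remain intact.

## Limitations

The adjustment constants 1.89 and 2.4 are corpus medians, not
population-specific truths; where a population's true ratios differ, the
constrained models converge to the constants, not to that population's
truth. The stillbirth adjustment anchors entirely on the D0–1 hazard, so it
inherits any bias that the weighting step fails to remove from D0–1 —
notably when heaping has depleted the days 2–6 denominator. Uncertainty
intervals for adjusted rates are out of scope, as are covariate-stratified
adjusted rates and month-level mortality beyond day 9.
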