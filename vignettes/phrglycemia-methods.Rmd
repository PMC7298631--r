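---
title: "Methods: cohort rules, the decline statistic, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort rules, the decline statistic, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrglycemia)
```

## What the package computes

`phrglycemia` implements a retrospective analysis of whether *continuous*
engagement with a mobile personal health record (PHR) app is associated with
better glycemic control in a diabetes cohort. The raw material is two data
streams: app-usage logs (one row per data-entry event in the blood-glucose
"sugar" diary or the diabetes calendar) and EMR extracts (HbA1c laboratory
results, ICD-10 diagnoses, demographics). The pipeline

1. validates and normalizes the four CSV inputs (`read_log()`,
   `read_hba1c()`, `read_diagnoses()`, `read_users()`,
   `filter_post_creation()`);
2. applies the inclusion flow and engagement classification
   (`build_cohort()`);
3. scores the diabetes complications severity index (`score_dcsi()`);
4. fits per-patient HbA1c trend statistics (`compute_trend_summaries()`);
5. runs the group-comparison and covariate-adjustment battery and assembles
   the report (`run_pipeline()`).

A synthetic-data generator (`generate_dataset()`) with per-user ground truth
stands in for hospital data, so every stage is testable end to end.

## Cohort rules

**Appropriate measurement.** A user enters the analysis only with at least
two HbA1c results whose first-to-last span is *strictly* greater than 100
days, and with the app account created inside that span. The rationale is
numerical, not clinical: the trend slope over a short span is dominated by
assay noise, and the span-normalised decline statistic would explode.

**Diabetes criteria.** Any ICD-10 diagnosis whose 3-character root is E08,
E09, E10, E11 or E13 — codes are matched on the root, so `E11.9` counts —
or a first HbA1c at or above the 6.5% diagnostic cutoff. All 6.5%
thresholds in the package are inclusive on the high side (`>= 6.5` is
"high"), matching the table row labels of the source analysis.

**Continuous use.** The engagement rule is "data entered in the sugar
function at least once per week, sustained for at least four weeks
(28 days)". That phrase admits several formalisations;
`classify_continuous()` implements three, selected by `rule`:

* `"anchored_bins"` (default): days are binned into consecutive 7-day bins
  anchored at the user's first sugar event; the user is continuous iff some
  run of 4 or more consecutive bins are all non-empty. Anchoring at first
  use avoids making the outcome depend on the weekday the user happened to
  start.
* `"calendar_weeks"`: the same run condition over Monday-anchored calendar
  weeks.
* `"window28"`: some 28-day window exists whose four 7-day bins are all
  non-empty.

All three agree on the canonical worked examples (days {0,7,14,21} is
continuous; {0,14,21,28} is not; {0,3,8,16,22,27} is), and all are
invariant to duplicate same-day events and event order. One caveat
discovered during implementation: *adding* events is only guaranteed to
preserve a continuous classification under `"window28"`. Under the anchored
reading, an added event that is earlier than every previous event shifts
the bin anchor; for example days {0,13,14,27,28} are continuous, but adding
an event 6 days earlier re-bins them to {0,2,4} and breaks the streak. The
monotonicity property is therefore tested for `"window28"` only, and the
anchored default is tested against the worked examples.

The rule tolerating a missed week inside a longer streak was deliberately
not invented: the strict reading is the default and the alternatives are
config-gated.

## The decline statistic

For each patient, HbA1c is regressed on days since the first measurement by
ordinary least squares. The fit is the closed-form two-parameter solution
(`fit_trend()`); using days-since-first as the abscissa makes slope,
r-squared and decline invariant to translating all dates, and keeps the
normal equations well-conditioned. Then

> decline = slope (%/day) x span (days) / 100,

where span is the calendar-day difference between the last and first
measurement (no +1). By OLS algebra, 100 x decline is *identically* the
change in the fitted line between the first and last measurement dates, so
a decline of -0.0044 reads as "the fitted HbA1c fell by about 0.44
percentage points over this patient's whole span". The identity is enforced
at machine precision in the test suite. Note the identity involves the
*fitted* change: a patient whose raw first and last values are 6.9 and 6.4
need not have decline -0.005 unless the points are collinear.

Numerical conventions:

* r-squared is defined as 1 when the fit is exact — two points, or all
  values equal (`SStot = 0`) — and clamped to [0, 1] against floating-point
  droop.
* n < 2 measurements or all-identical dates raise typed errors
  (`phr_argument_error`, `phr_degenerate_error`); they never return NaN.
* Duplicate same-day measurements are retained as separate OLS points; the
  source analysis gives no guidance, and averaging them is a one-line
  pre-processing step a site can apply.
* The per-patient SD is the sample SD (n-1 denominator) of the raw values.
* Measure frequency is n / span per user (the mean of per-user ratios, not
  the ratio of means).

## DCSI scoring

Seven complication categories (retinopathy, nephropathy, neuropathy,
cerebrovascular, cardiovascular, peripheral vascular, metabolic) are scored
0/1/2 — neuropathy 0/1 — and summed to a 0-13 total. Within a category the
score is the *maximum* severity among matched codes, never the sum. Codes
are matched by longest prefix after normalization (uppercase, dot
stripped), so a site mapping can mix 3- and 4-character prefixes and the
more specific entry wins.

The ICD-10-to-category table ships as an editable CSV asset
(`inst/extdata/dcsi_mapping_default.csv`, loaded by `dcsi_load_mapping()`).
The published claims-data adaptation of the index is cited but not
reprinted by the source study, so the shipped table is a reconstruction in
its spirit and is deliberately easy to replace with a local mapping.
Urinalysis-based severity upgrades are excluded by design — the study
setting had no urine laboratory data — so only diagnosis codes are ever
consulted.

## The statistical battery

All tests are two-sided; no multiple-testing correction is applied (the
source analysis used none; `adjust_bh()` exists for users who want one).

* **Student t**: pooled variance.
* **Wilcoxon rank-sum**: normal approximation with tie correction and no
  continuity correction — group sizes in the thousands make exact
  enumeration pointless.
* **Two-proportion z**: pooled variance, no continuity correction, chosen
  so that z² equals the Pearson chi-square on the same 2x2 table; the test
  suite checks that identity.
* **Mood's median test**: 2xk chi-square of counts above vs at-or-below the
  pooled median (ties counted "below").
* **Chi-square over category distributions**: categories empty in *both*
  groups are dropped first (a chi-square cell with zero expectation in
  every group is undefined); an expected cell below 1 flags the result.
* **Normality**: Shapiro-Wilk and the D'Agostino K-squared omnibus test,
  with a combined "normal" verdict only when every applicable test is
  non-significant at alpha = 0.05. D'Agostino is implemented from the
  standard skewness/kurtosis z transformations (no R package in the stack
  provides it) and is pinned to a frozen SciPy oracle in the tests; it
  requires n >= 8. R's `shapiro.test()` caps n at 5000, so larger samples
  are thinned deterministically to 5000 evenly spaced order statistics —
  a shape-preserving reduction that keeps the verdict reproducible.
* **ANCOVA**: `decline ~ continuous_use + age + sex + first_hba1c + dcsi +
  sugar_weeks + weeks_before_start + sugar_count`, per-term F tests with 1
  numerator df. Sums of squares are Type II (recorded in the report
  metadata); with no interaction terms these are exactly the drop-one F
  tests, which is how they are computed. Rank deficiency is an error that
  names the collinear terms, not a silent NA.
* **Logistic regression**: for users with first HbA1c >= 6.5%, success =
  last HbA1c < 6.5%, same eight covariates, ML fit with intercept. Coding
  is recorded: continuous = 1, male = 1, regulated = 1. Complete or
  quasi-complete separation (fitted probabilities pinned to 0/1 with
  exploding coefficients) and non-convergence raise typed errors.

## The synthetic world

The generator's defaults *are* the published cohort's printed group
statistics: group sizes 133/7320; age 53.59 +/- 9.89 vs 57.58 +/- 11.95;
male 82.7% vs 66.37%; first HbA1c 7.86 +/- 1.78 vs 7.51 +/- 1.62;
12.44 +/- 6.90 vs 11.90 +/- 6.82 measurements over 1254 +/- 461 vs
1336 +/- 445 days; account creation 546 +/- 348 vs 712 +/- 377 days after
the first measurement; decline -0.00533 +/- 0.0144 vs -0.00278 +/- 0.0137;
complication category prevalences as printed. Where a needed parameter is
not printed, it is derived from printed quantities or chosen once:

* **Decline-covariate correlations** (`decline_cor`). The adjusted model in
  the source reports F = 3054.9 for the first-HbA1c term at n = 7453,
  which implies a partial correlation near -0.54 between decline and first
  HbA1c (patients starting higher decline more); the days-before-start and
  age terms' F statistics imply roughly +0.14 and +0.03. The generator
  embeds these as defaults and shrinks the residual SD so the marginal
  decline SD stays at the printed value. Covariates are standardised
  *in-sample*: truncation (days-before-start must fit inside the feasible
  calendar window) shifts nominal z-scores, and in-sample centring keeps
  the group's marginal decline mean at `decline_mean`.
* **Measurement noise** (`hba1c_noise_sd` = 0.70 / 0.60). The printed group
  means of the per-patient HbA1c SD are 0.832 and 0.719. A per-patient SD
  decomposes as sqrt(noise² + trend-spread²), and the trend spread is fixed
  by the printed decline distribution ((100 x decline)² / 12 under even
  sampling); solving gives 0.704 and 0.595.
* **Engagement counts.** Continuous users' sugar event counts are
  log-normal with median 97 and sdlog 1.086, matching the printed median
  and IQR (97, 43-186); the per-user event-count distribution is not
  otherwise stated, so the log-normal is a modelling choice, not a claim.
  Noncontinuous emitters (3.95% of the group) produce 1 + Poisson(4)
  events, matching the printed group mean of 0.2 events/user.
* **Timeline.** Account creation is drawn uniformly over the app's
  operating window; days-before-start is a truncated normal clipped into
  the measurement span (and at least 28 days before the last measurement
  for continuous users), so the Figure-style constraint "account created
  during HbA1c measurement" holds by construction *and* the printed
  days-before-start means are recovered. Measurement days are evenly
  spaced with +/-10% jitter of the gap, first and last fixed, preserving
  the exact span. Ages are truncated at 18 and HbA1c values clipped to
  [4, 16]; normal draws are re-sampled on truncation so means are not
  distorted by a boundary point mass.
* **Diabetes codes.** Every generated user carries an E08-E13 root code
  (`diabetes_code_prob = 1`). The stated world emulates the
  already-selected diabetic cohort, and the round-trip requirement — truth
  labels reproduced by the pipeline for every user — needs full inclusion;
  with a lower probability, users with first HbA1c < 6.5 and no code would
  be excluded, a *selected* subgroup whose removal biases the recovered
  decline means through the first-HbA1c link.

**Guaranteed round trip.** Continuous users' sugar events are constructed
to satisfy the weekly rule (one event in each of at least four consecutive
anchored bins, first event at day 0; extra events can only add to bins).
Noncontinuous emitters violate it structurally: all their events fall
inside a single 13-day burst, which can occupy at most two 7-day bins under
any of the three rule readings.

**What the generator does not emulate** — and hence what a green test does
not establish: visit-scheduling policy (measurement dates are jittered
grids, not clinic calendars), medication changes or any within-day glucose
structure, correlation between app engagement and measurement cadence
beyond the printed group differences, non-linear HbA1c trajectories
(regression to the mean appears only through the decline-covariate link),
and coding practice artefacts in the EMR (every diagnosis is a clean,
mappable code). Green acceptance tests establish that the *pipeline*
recovers the parameters of this stated world, not that the world captures
every feature of hospital data.

## Calibration of the adjusted model

`simulate_analysis_table()` draws the per-user covariate-plus-decline table
directly from the generator's covariate model, skipping trajectory and log
synthesis, so thousands of ANCOVA fits are affordable. Both groups share
the reference covariate distributions and `effect` injects a decline shift
for continuous users. This group-independence is the point of the harness:
in the real cohort the engagement covariates (sugar weeks, sugar count)
nearly encode the group label, the group term's partial information
collapses, and no simulation could — or should — show high power there
(the source's own adjusted continuous-use effect was only marginally
significant). The acceptance suite uses the harness to verify that the
ANCOVA's type-I error is 0.05 +/- 0.02 under the null and that an injected
-0.003 effect at the study's group sizes is detected in at least 80% of
simulated cohorts.

## Known limitations

* The published headline p-values are not reproducible by anyone without
  the hospital dataset; the package asserts formula-level correctness,
  printed-count arithmetic, simulation calibration and parameter recovery
  instead.
* The shipped DCSI mapping is a reconstruction (see above); sites with the
  licensed table should substitute it via `dcsi_load_mapping(path)`.
* Published percentages mix rounding conventions between table columns
  (some are rounded half-up, some truncated); `proportion()` supports both
  and defaults to half-up.
* The generator draws the diabetes-calendar stream independently of the
  sugar stream; any real correlation between the two functions' usage is
  not modelled.
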