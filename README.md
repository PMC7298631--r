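# phrglycemia

Does *continuous* use of a mobile personal health record (PHR) app go along
with better glycemic control? `phrglycemia` is an R implementation of the
retrospective cohort analysis behind that question, for biostatisticians and
digital-health researchers who want to run, audit or re-parameterise the
whole pipeline: from raw app-usage logs and EMR extracts to the adjusted
group comparisons.

## What it computes

**Inputs** (CSV): an app-usage log (one row per data-entry event in the
blood-glucose "sugar" diary or the diabetes calendar), HbA1c laboratory
results, ICD-10 diagnosis records, and demographics with account-creation
dates.

**Cohort.** Users enter the analysis with an *appropriate measurement
history* — at least two HbA1c results spanning strictly more than 100 days,
account created inside the span — and *diabetes* (any ICD-10 code with root
E08/E09/E10/E11/E13, or first HbA1c ≥ 6.5%). Included users are
*continuous* if their sugar-diary events occur at least once per week
sustained over ≥ 4 weeks (28 days); the formalisation of that rule is
configurable (anchored 7-day bins by default).

**Per-patient trend.** HbA1c is regressed on days since the first
measurement (OLS). The central statistic is the span-normalised

```
decline = slope [%/day] × span [days] / 100
```

which, by OLS algebra, is identically the fitted HbA1c change over the
patient's whole span divided by 100 — a decline of −0.0044 means the fitted
HbA1c fell by ≈ 0.44 percentage points. Alongside it: r², the per-patient
SD, measurement frequency, and the (first, last) ≥ 6.5% regulation class.

**Severity.** The diabetes complications severity index (DCSI, 0–13) is
scored from ICD-10 codes over seven complication categories (max severity
per category; neuropathy capped at 1; urinalysis criteria excluded). The
code mapping ships as an editable CSV asset.

**Comparisons.** Student t / Wilcoxon rank-sum / Mood's median /
pooled-z / chi-square group comparisons with Shapiro–Wilk + D'Agostino
normality checks; an ANCOVA of decline on continuous use plus seven
confounders (per-term Type II F tests); and a logistic model of successful
regulation (first ≥ 6.5% → last < 6.5%) on the same covariates.

**Synthetic cohort.** `generate_dataset()` draws a full PHR + EMR dataset
whose group statistics default to the published cohort's (n = 133
continuous / 7320 noncontinuous), with per-user ground truth, so the whole
pipeline is testable without any hospital data.

## Worked example

```r
library(phrglycemia)

cfg    <- generator_config(n_continuous = 50, n_noncontinuous = 500, seed = 42)
report <- run_pipeline(cfg)
print(report)
#> <phr_report>
#>   accounts 550 -> appropriate 550 -> diabetes 550 -> continuous 50 / noncontinuous 500
#>   continuous: mean decline -0.00334 (n=50)
#>   noncontinuous: mean decline -0.00421 (n=500)
```

Every account passed the inclusion flow (the generator emulates the
already-selected cohort), and the engagement classifier reproduced the
generator's 50/500 group split exactly. At this reduced scale the two
groups' mean declines are statistically indistinguishable — separating
declines of −0.00533 vs −0.00278 against SDs of ≈ 0.014 needs the full
cohort size, which is the point of running the battery at n = 133/7320.

```r
report$table2[, c("term", "f", "p_value")]          # ANCOVA, Type II F
#>   term                        f  p_value
#> 1 continuous_use          1.07   0.30
#> 2 age                     0.59   0.44
#> 3 sex                     0.42   0.52
#> 4 first_hba1c           216.25   2.0e-41
#> 5 dcsi                    2.74   0.098
#> 6 sugar_weeks             4.75   0.030
#> 7 weeks_before_start      5.44   0.020
#> 8 sugar_count             1.80   0.18
```

The dominant first-HbA1c term is the built-in regression-to-target link
(patients who start higher decline more); at this scale it is the only
overwhelming effect, exactly as the covariate model prescribes.

```r
report$table3[, c("regulation", "continuous_n", "continuous_pct", "p_value")]
#>   regulation continuous_n continuous_pct p_value
#> 1 low_low               3            6.0   0.19
#> 2 low_high              4            8.0   0.33
#> 3 high_low              8           16.0   0.67
#> 4 high_high            35           70.0   0.067
```

`report$metrics` holds the per-patient statistics,
`plot_decline_lines(report$metrics)` draws the decline-pattern figure, and
`write_report(report, "out/")` serializes everything (JSON + one CSV per
table). A thin CLI over the same functions lives at
`system.file("scripts", "phr-glycemia.R", package = "phrglycemia")`
(`simulate | report | all`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic cohort at the published group sizes
(133/7320) with the given seed, runs the installed package's full pipeline
on it — inclusion flow, engagement classification, DCSI, per-patient trend
metrics, comparison battery — prints the cohort flow and per-group decline
summaries, and writes the acceptance JSON to `--out`.

## Further reading

The methods vignette (`vignettes/phrglycemia-methods.Rmd`) documents the
cohort-rule interpretations, the decline identity and its numerical
conventions, the test battery's exact conventions, how every generator
default is anchored to (or derived from) the published group statistics,
and what the synthetic world deliberately does not emulate.
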