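---
title: "Methods: glycemic metrics, stratification and simulation in glycostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycemic metrics, stratification and simulation in glycostrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycostrat)
```

## The problem

Intermittently scanned continuous glucose monitors (isCGM) log interstitial
glucose on a fixed cadence (every 15 minutes for the sensors this package
targets) and additionally record a reading each time the wearer scans the
sensor. For a clinic following hundreds or thousands of pediatric patients
with type 1 diabetes, the raw per-patient exports must be turned into the
consensus glucometric metric vector, screened for data quality, classified
against agreed targets, and summarised at cohort level. glycostrat
implements that pipeline end to end, plus a calibrated simulator so the
whole pipeline can be exercised and tested without any patient data.

## Metric definitions and conventions

All range metrics are **absolute cumulative times divided by total monitored
time** over a single analysis window. The window is the last 14 days of the
series (the consensus recommendation for estimating longer-term control,
together with at least 70% sensor usage), anchored at the latest reading,
inclusive at the early boundary. Each historic reading stands for one
nominal 15-minute interval; no interpolation or gap-filling is performed, so
monitored time is simply `readings x cadence`. Both `window_days` and
`cadence_min` are configuration parameters (`default_config()`).

The five clinical ranges partition the positive axis:

| range | interval (mg/dL) |
|-------|------------------|
| TBR2  | (0, 54)          |
| TBR1  | [54, 70)         |
| TIR   | [70, 180]        |
| TAR1  | (180, 250]       |
| TAR2  | (250, Inf)       |

The published wording ("between 70 and 180" and so on) does not pin the
endpoints; the convention above keeps 70 and 180 in range, matches common
ambulatory-glucose-profile practice, and makes the five ranges a true
partition (a brute-force sweep over a 0.1 mg/dL grid is part of the test
suite). Scan readings never enter range times, mean, SD, CV or GMI: they
would double-count intervals already covered by the historic log and are
biased toward moments the wearer chose to look. They feed only the
scan-frequency metric. Whether scan rows should additionally count toward
monitored time is unknowable from export files alone, so it exists as a
config switch (`io$count_scans_in_monitored`), default off.

Summary glucose uses the sample (n-1) SD, and CV = 100 x SD / mean. The
glucose management indicator uses the standard linear regression
GMI(%) = 3.31 + 0.02392 x mean glucose (mg/dL); it is an external constant,
not a fitted quantity. Sensor usage is the fraction of expected historic
readings present (96/day at the 15-minute cadence), capped at 100% because
overlapping sensor sessions can exceed the expectation.

## Quality filtering

A patient is excluded when any of the following holds: an essential
demographic field (age, hospital id) is absent or non-numeric; any retained
glucose value falls outside the device-plausible span [40, 500] mg/dL; no
historic readings survived parsing; or sensor usage is strictly below 70%
(the gate is printed as "< 70%", so exactly 70% is kept). Filtering never
raises on bad data — it excludes and logs, one record per patient, ordered
by patient id, so that `included + excluded = cohort` always holds and the
filter is idempotent.

## The three classifiers

**ATTD-2019 compliance.** Seven targets, all read with strict inequalities:
TIR > 70%, TAR1 < 25%, TAR2 < 5%, TBR1 < 4%, TBR2 < 1%, CV < 36%, and the
composite mean < 154 mg/dL with SD < 29 mg/dL. A patient at exactly 70% TIR
does not meet the TIR target. `all_met` aggregates the five range targets;
`level1_met` aggregates TIR, TBR1, TAR1.

**Four-colour triage.** The published band rules are ORs over TIR, TBR1 and
TAR1 and can disagree across variables (green-level TIR with orange-level
TBR1, say). Evaluation is therefore severity-max: red, orange, yellow are
tested in that order and the most severe band triggered wins — the only
order-independent reading, and the clinically conservative one. The printed
rules also leave three boundary values unassigned (TIR = 40, TBR1 = 4,
TBR1 = 20); each resolves to the more severe adjacent band. The whole
decision table lives in `andiacare_thresholds()` so the choice is auditable
and overridable.

**Glycemic Risk Index.** GRI = 3.0 x %time < 54 + 2.4 x %time 54–70 +
1.6 x %time > 250 + 0.8 x %time 180–250, capped at 100, zoned A [0, 20],
B (20, 40], C (40, 60], D (60, 80], E (80, 100]. The published zones are
integer bands (0–20, 21–40, ...); reading them as half-open real intervals
zones every continuous score. The hypo/hyper components reuse the metric
module's TBR/TAR fields rather than recomputing with different boundaries.
A patient missing any component gets no numeric score and the zone label
`not_allowed`, but still receives a triage category — the classifier
cross-tab keeps such patients in a dedicated column.

## Cohort statistics

Age bands are half-open low-inclusive — [4, 6), [6, 12), [12, 18] — so
every age maps to exactly one band; ages outside [4, 18] are flagged
`out_of_band`, excluded from band tables but kept in cohort totals. Centre
sizes follow the pediatric-network convention small < 50, medium 50–150
(both ends inclusive), large > 150 patients.

Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7). Normality is screened per sample with
Shapiro–Wilk at alpha = 0.05; comparisons then use the t test when both
samples pass and the Wilcoxon rank-sum test otherwise, and correlations use
Pearson versus Spearman by the same rule. Group comparisons are **unpaired**
two-sample tests: the age bands contain disjoint patients, so a paired
procedure is not meaningful for this design. Every emitted table forms one
Benjamini–Hochberg family (all pairwise tests of a comparison table
together; all pairs of a correlation table together); the family boundary
is a design choice, stated here because no external definition exists.
Constant (zero-variance) samples are routed to the rank-based tests, since
the Shapiro–Wilk statistic is undefined for them.

## The synthetic cohort generator

Glucose is positive and strongly autocorrelated at the 15-minute cadence,
so the simulator models log glucose as a stationary AR(1) process with
marginal N(mean_log, sd_log^2) and lag-one correlation rho (default 0.9),
exponentiates, truncates to the device span [40, 500] and rounds to integer
mg/dL. Historic readings sit on the exact cadence grid and are dropped
independently with `dropout_prob`; scan events arrive as a Poisson count
per day at band-specific rates, placed uniformly in the day, and carry the
concurrent grid glucose. The generated files use the same export dialect
the parser reads, so the simulator exercises the full pipeline including
I/O. Everything is a pure function of the cohort spec, including its seed.

`default_cohort_spec()` encodes the study conditions the package was built
around: 124 / 776 / 1315 patients in bands 4–6 / 6–12 / 12–18, band scan
rates 20.38 / 13.75 / 9.12 scans/day, and 18 centres (3 large, 5 medium,
10 small; roughly 50% / 28% / 22% of patients).

**Calibration.** `calibrate_to_marginals()` finds the (mean_log, sd_log)
whose band-mean range percentages match a published profile: a dense
analytic grid search first (the marginal occupancy of each range has a
closed form under the lognormal, with band edges at 53.5 / 69.5 / 180.5 /
250.5 to account for integer rounding), then the leading candidates are
re-scored by simulating 100 patients through the actual metric pipeline at
a fixed seed, and the simulation-verified best is returned. The objective
is the maximum absolute deviation, with 5 percentage points as the default
acceptance tolerance. Published summary tables print range profiles in two
conventions; the calibrator accepts both. Exclusive five-way profiles sum
to 100. Level-1-cumulative profiles report TAR1 as total time above 180
(including above 250) and TBR1 as total time below 70 (including below 54),
so TIR + TAR1 + TBR1 is about 100 — the convention is detected from the
sums, and anything matching neither is rejected as infeasible. The default
band models were produced by exactly this routine against the published
band profiles (achieved error about 2 points per band).

**What the simulator does not emulate.** All patients of a band share one
trace model, so between-patient spread of TIR comes only from sampling
noise of ~1300 autocorrelated readings (a few points of SD) rather than the
~19-point SD real cohorts show. Band-level *means* are matched; the
fraction of simulated patients crossing a fixed threshold such as TIR > 70%
is therefore much narrower than in real data, and passing tests on
simulated cohorts demonstrates pipeline correctness, not epidemiological
realism. There is also no meal/insulin physiology, no diurnal structure,
and no correlation between scan frequency and control.

## Numerical choices and degenerate inputs

Duplicate historic timestamps collapse to the last occurrence with a
warning (deterministic and auditable). Rows with unparseable timestamps or
non-numeric glucose are dropped and counted; a file yielding no valid rows
is an error. Timestamp parsing uses an explicit configurable pattern
(ISO-8601 by default, a day-first alternative documented) — never locale
guessing, which silently swaps day and month. Patients whose series cannot
support a metric (fewer than two historic readings, say) get NA metrics and
an entry in a failures log rather than aborting the cohort; downstream,
missing GRI components map to `not_allowed` and missing triage inputs to
`unclassifiable`. Ties in the TIR-ordered stacked-range rows break by
patient id so report data files are byte-reproducible.

## Problem sizes used in the test suite

The automated tests run the pipeline on generated cohorts of 5–50 patients,
calibrate against the three published band profiles at 100 patients per
band, and check the type-I error of the group-comparison machinery with
1000 label permutations of a 60-patient null cohort — sizes chosen so the
full suite completes in seconds while keeping Monte-Carlo error well inside
the asserted tolerances. The full-scale default spec (2215 patients)
generates in a few minutes and is intended for interactive use.

## Known limitations

Only the pinned export dialect and a generic long CSV are parsed — no
real-time-CGM or pump formats, and no PDF profile parsing. No imputation or
partial-window rescue of low-usage patients. No multivariate modelling: the
per-patient feature set (age, centre, metrics) is deliberately minimal. The
HTML report is a static self-contained file with client-side sorting; its
aesthetics are not part of the tested contract, the data files underneath
it are.
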