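---
title: "Methods: temporal risk profiling of hypoglycemia from CGM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal risk profiling of hypoglycemia from CGM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmtempo)
```

## The problem

Children with hyperinsulinism (HI) — dysregulated insulin secretion with
suppressed ketogenesis — suffer recurrent hypoglycemia that carries a real
risk of brain injury, and the risk is not uniform over the day. Continuous
glucose monitoring (CGM) devices report subcutaneous glucose at a nominal
5-minute epoch over days of wear, which makes it possible to ask *when*
hypoglycemia happens: which hours of the clock carry elevated risk, how that
risk differs between clinical subgroups (age, genotype, medication), and how
the picture changes with the hypoglycemia threshold chosen. `cgmtempo`
implements that analysis as a reusable pipeline: trace ingestion and
normalization, episode segmentation, hour-of-day minute accounting, windowed
comparisons, contingency and rank tests, threshold sweeps — plus a synthetic
cohort generator with known ground truth so every stage is testable without
patient data.

## Definitions and the episode model

All glucose is carried in mmol/L (1 mmol/L = 18.016 mg/dL; the clinical
pairing 3.5 mmol/L = 63 mg/dL is consistent with this factor to rounding).
A reading is **hypoglycemic** when its value is *strictly* below the
threshold (default 3.5 mmol/L); a value exactly at threshold is not. A
**hypoglycemia event** is a maximal run of consecutive hypoglycemic
readings. Consecutiveness requires adjacency in the trace *and* an
inter-reading gap of at most `max_gap_minutes` (default 1.5 nominal epochs
= 7.5 min): a longer gap breaks the run, so unobserved time is never
imputed as hypoglycemia. Each reading stands for the half-open interval
`[t, t + 5 min)`, so

* monitored minutes = 5 × number of readings (gaps contribute nothing),
* event duration = 5 × number of below-threshold epochs in the run — never
  `end − start`, which would silently bridge gaps,
* the minimum event is a single epoch (5 minutes).

The **nadir** is the minimum glucose within an event. Dexcom-style devices
only report down to a floor of 2.2 mmol/L; textual `Low` readings are
imputed at the floor and flagged, and an event whose nadir sits at the
floor carries `nadir_clipped = TRUE` because the true minimum is unknown
(censored). Clipped-low readings are below any analysis threshold above the
floor and count fully toward hypoglycemic minutes. A **prolonged** event
lasts strictly more than 30 minutes, which at 5-minute epochs means at
least 35.

Timestamps are naive local clock times at minute resolution, stored without
timezone or daylight-saving arithmetic, because the scientific question is
about the wall clock. Duplicate timestamps keep the first value (with a
warning when values conflict). Exclusion intervals — e.g. data recorded
during an in-hospital controlled fast — are half-open `[start, end)` and
simply delete the covered readings before analysis.

## Hour-of-day accounting and clock windows

Each reading credits its whole epoch to the hour bin of its timestamp: an
epoch starting 03:55 belongs wholly to hour 3. No splitting rule is
applied; at 5-minute granularity the error of this convention is bounded by
one epoch per hour boundary and it keeps every identity exact (hourly
monitored, hypoglycemic and event-start totals each sum to the cohort
totals). Event *starts* are binned by the hour of the first below-threshold
reading.

A clock window is half-open on whole hours, `[start:00, end:00)`, and may
cross midnight: the "early hours" window is `[03:00, 07:00)` (width 4 h,
expected share of an evenly distributed quantity 4/24 = 16.7%), and an
evening window such as `[18:00, 01:00)` has width 7 h. A window summary
reports inside/outside monitored and hypoglycemic minutes, percent time
hypoglycemic on each side, the share of all hypoglycemic minutes inside
versus that expected share, and the risk ratio (inside percent / outside
percent). Pooling across patients sums minutes — the counting unit of the
published tables — while per-patient profiles remain available for
sensitivity analyses.

In prose-style output percents are shown to 1 decimal and subgroup-table
shares to 2; all stored values are unrounded. Some published subgroup
tables appear to truncate rather than round (e.g. a share of 38.0952
printed as 38.09), and the age-subgroup outside-window denominators of one
published table are internally inconsistent (92,840 + 37,150 ≠ 123,490);
the package documents rather than reconciles such values, and its own
outputs always satisfy the partition identities.

## Statistical comparisons

Two tests cover the comparisons reported in this literature:

* **Pearson chi-square on a 2×2 minute table**, built from a window summary
  as `(inside hypo, inside not-hypo, outside hypo, outside not-hypo)` and
  evaluated in closed form, `N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
  The continuity correction is off by default — minute counts are in the
  tens of thousands, where Yates is immaterial — but available.
* **Mann–Whitney U** for continuous variables, with U counted as
  `#(x > y) + ½ #(x = y)` pairs. For `min(n₁, n₂) ≤ 8` the two-sided
  p-value is an exact enumeration over all `C(n₁+n₂, n₁)` group
  assignments (valid under ties); otherwise the tie-corrected normal
  approximation is used. Degenerate input (all pooled values identical)
  returns p = 1 with a note.

P-values are two-sided throughout and no multiple-testing correction is
applied, matching the practice of the analyses this package reproduces.

A caveat that the package makes explicit rather than hiding: hypoglycemic
minutes are serially clustered into events (mean event length is several
epochs), so a minute-level chi-square treats correlated minutes as
independent and is strongly anticonservative — under a uniform-hazard null
its rejection rate at α = 0.05 is far above 5% (0.83 in the package's own
calibration study of 200 simulated null cohorts). The pipeline therefore
reports it as the descriptive, literature-comparable statistic, and
additionally provides `window_start_test()`: a goodness-of-fit chi-square
of the number of *events starting* inside the window against the
monitored-minute expectation. Event starts are approximately independent
units, and the same calibration study measures its size at 0.05. This
event-level test is the one the package treats as confirmatory for
windowed clustering.

Subgroup comparisons split the cohort by metadata — age at 10 months
(`age ≥ 10` vs `< 10`; the published 16/7 split places a child aged
exactly 10 months in the older group, which forces the ≥ convention),
mutation-positive vs -negative (genetic testing not done excluded),
on- vs off-medication, or diagnosis — and report each group's window
summary, minute-table chi-square, and a qualitative tendency label from
risk-ratio bands: ≥ 3 "++", 2–3 "+", 1.5–2 "−", 1–1.5 "−−", "evenly
distributed" when the risk ratio is below 1.2 and the hypo-minute share is
within 5 points of the expected share, and "below average" below 1. The
bands are a documented package convention for readable tables, not a
clinical scale.

Threshold sweeps rerun detection and windowing at each requested threshold
(defaults 3.9, 3.5, 3.0 mmol/L — common pediatric definitions). Thresholds
at or below the 2.2 mmol/L device floor are refused, since every clipped
reading would be ambiguous there. Total hypoglycemic minutes are
non-increasing as the threshold falls (enforced as an internal invariant);
event *counts* need not be monotone because runs can split.

## The synthetic cohort generator

No public CGM dataset exists for this population, so the package ships a
generator whose defaults emulate the statistical structure reported for a
monitored HI cohort, and those defaults are fixed study conditions rather
than tuning knobs:

| parameter | default | what it emulates |
|---|---|---|
| `n_patients` | 47 | cohort size |
| `days_range` | 4–10 (uniform) | per-patient wear time |
| `epoch_minutes` | 5 | device reporting epoch |
| `baseline_onset_prob` | 0.005 /epoch | ≈ 1.9–2 events/day/patient |
| `window`, `window_multiplier` | 03:00–07:00, 2.5 | early-hours hazard elevation (reported risk ratios 2–3×) |
| `duration_mean_min`, `duration_sd_min` | 35, 57 | heavy right tail of event durations |
| `nadir_mean`, `nadir_sd` | 3.1, 0.37 | event nadirs, truncated at the 2.2 floor |
| `baseline_mean`, `baseline_sd`, `baseline_rho` | 5.5, 0.8, 0.9 | AR(1) normoglycemic glucose |
| `dropout_prob` | 0.02 /epoch | sensor dropout |
| `frailty_sigma` | 0.8 | per-patient overdispersion of event counts |

Generation is a two-state semi-Markov process on the epoch grid. In
normoglycemia, glucose follows the AR(1) process bounded below at
`threshold + 0.3` so that baseline noise never crosses the threshold; at
each epoch an event starts with probability
`baseline_onset_prob × frailty × (window_multiplier inside the window)`.
An event draws its duration from a lognormal moment-matched to the target
mean/SD (durations mean < SD is exactly the lognormal's territory),
discretized to whole epochs with minimum 1, and its nadir from the
truncated normal; within the event glucose follows a V-shaped dip strictly
below threshold reaching the nadir at the midpoint — the simplest shape
consistent with a defined nadir, with no claim of physiological realism.
One normoglycemic epoch is enforced after each event so that true events
are separated; without it two events could abut and merge under the run
definition, and the exact-recovery contract below could not hold. Readings
are then thinned by i.i.d. dropout and clipped at the floor/ceiling.
Per-patient seeds, frailties and wear times derive deterministically from
the master seed: identical configuration gives identical cohorts,
bit-for-bit through the normalized CSV.

What the generator deliberately does **not** model: meals, insulin or any
physiology; burst (non-independent) missingness; device noise spectra;
between-hour structure beyond the single window multiplier. Passing
recovery tests on synthetic cohorts therefore demonstrates that the
*pipeline arithmetic* is correct under known ground truth — not that the
generator resembles any particular patient.

`recovery_check()` closes the loop: it reruns detection on a simulated
cohort and compares detected events and minutes against ground truth (with
dropout 0 the match is exact — dropout can split events across the 7.5-min
gap rule, which is the detector honestly refusing to bridge unobserved
time), and estimates the configured hazard multiplier. The estimator is
the event-onset rate ratio — starts per at-risk (non-hypoglycemic
monitored) minute inside vs outside the window — with a patient-level
bootstrap interval. The minute-based risk ratio is reported alongside but
is *not* the estimator of the multiplier: minutes of events that start
near 07:00 spill outside the window, diluting it toward 2 when the onset
hazard ratio is 2.5.

## Numerical and edge-case conventions

* SDs are sample SDs (n − 1); the SD of a single observation is reported
  as 0 with a warning so demographic tables stay total-safe.
* Records with missing age are excluded from means with a logged count.
* Zero monitored minutes (cohort-wide, or inside a requested window) is a
  hard error, not a silent NaN; a zero-hypoglycemia profile yields percent
  0 and an NA risk ratio, flagged rather than fabricated.
* Chi-square cells are coerced to doubles before the closed form — minute
  counts overflow 32-bit integer arithmetic.
* `parse_cgm_csv` fails hard, naming the row, on unparseable timestamps or
  glucose values; empty files and unknown units are errors, not guesses.

## Problem sizes used in the validation suite

The test-suite calibration studies use 200 replicate null cohorts of 8
patients × 4 days (uniform hazard) to measure the size of the windowed
tests and the convergence of the early-hours hypo-minute share to 16.7%,
one 47-patient cohort at multiplier 2.5 for hazard recovery (≈ 600 events;
bootstrap of 300 replicates), and 100 patients × 7 days for the
uniform-start binomial check (> 1000 events). These sizes give Monte-Carlo
error comfortably inside the asserted tolerances while keeping the whole
suite under a minute of simulation time.

## Known limitations

* Pooled-minute tests ignore within-patient correlation; the package
  documents this and offers the event-level test, but does not fit a
  hierarchical model.
* Hour attribution does not split epochs across bin boundaries.
* The V-shaped within-event profile and the lognormal frailty are
  conventions, isolated behind `simulation_config()` so alternatives can
  be swapped in.
* CGM accuracy against plasma glucose is out of scope, as is any
  prediction or alarm-behavior modelling.
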