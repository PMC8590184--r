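# cgmtempo

Temporal risk profiling of hypoglycemia from continuous glucose monitoring
(CGM) data.

Children with hyperinsulinism (HI) and related hypoglycemia disorders wear
CGM sensors that report glucose every 5 minutes for days at a time. The
clinically urgent question in those data is not just *how much* time is
spent hypoglycemic but *when*: which hours of the clock carry elevated
risk, whether that risk concentrates in the early hours of the morning,
how it differs between clinical subgroups, and how the picture shifts with
the hypoglycemia threshold. `cgmtempo` is for clinical researchers and
biostatisticians doing exactly this kind of time-of-day analysis.

## What it computes

* **Episode segmentation.** A hypoglycemia event is a maximal run of
  consecutive readings with glucose strictly below a threshold θ (default
  3.5 mmol/L), where a gap > 7.5 min breaks the run. Duration is
  5 min × epochs; minimum one epoch; nadir = min glucose, flagged as
  censored when at the 2.2 mmol/L device floor. Events lasting > 30 min
  are "prolonged".
* **Hour-of-day accounting.** Each reading credits 5 monitored minutes
  (and, if below θ, 5 hypoglycemic minutes) to the hour bin of its
  timestamp; percent time hypoglycemic per hour h is
  100 · hypo(h) / monitored(h).
* **Clock windows.** For any half-open window `[a:00, b:00)` — midnight
  wrapping allowed — the inside/outside percents, the share of all
  hypoglycemic minutes inside vs the expected width/24, and the risk
  ratio inside/outside.
* **Tests.** Pearson χ² (closed form, df 1) on the 2×2 inside/outside ×
  hypo/not-hypo minute table; Mann–Whitney U with exact small-sample
  enumeration; a calibrated event-start goodness-of-fit χ² for windowed
  clustering; subgroup comparison tables with tendency labels.
* **Threshold sweeps** over e.g. 3.9 / 3.5 / 3.0 mmol/L.
* **Synthetic cohorts.** A seeded semi-Markov generator with known ground
  truth (AR(1) baseline, lognormal durations, truncated-normal nadirs,
  per-patient frailty, a configurable early-hours hazard multiplier,
  dropout and floor clipping), plus `recovery_check()` to verify the
  pipeline recovers what was simulated.

Input formats: Dexcom-CLARITY-style CSV exports (EGV rows, mg/dL or
mmol/L, textual `Low`/`High`) and a normalized CSV dialect that
round-trips exactly.

## Worked example

Simulate a 47-patient cohort with a 2.5× early-hours hazard, run the
pipeline, and check what it recovers:

```r
library(cgmtempo)

cfg <- simulation_config(seed = 1)          # defaults: 47 patients, 4-10 days,
sim <- simulate_cohort(cfg)                 # 2.5x hazard in 03:00-07:00

dc     <- detection_config()                # theta = 3.5 mmol/L, gap 7.5 min
events <- do.call(rbind, lapply(sim$traces, detect_events, config = dc))
stats  <- cohort_event_stats(events, sim$traces, dc)
stats
#> <cohort_event_stats> 591 events over 47 patients
#>   time hypoglycemic: 19050 of 478500 minutes (4.0%)
#>   duration 32 (SD 46) min; nadir 3.1 (SD 0.29) mmol/L
#>   events/patient 12.6 (SD 10.5); 165 prolonged (>30 min) from 42 patient(s)

profile <- minutes_by_hour(sim$traces, events, dc)
ws <- window_summary(profile, clock_window(3, 7, "early hours"))
ws
#> <window_summary> early hours [03:00, 07:00)
#>   inside:  5710/79835 min hypoglycemic (7.2%)
#>   outside: 13340/398665 min hypoglycemic (3.3%)
#>   share of hypo minutes inside: 29.97% (expected 16.7%); risk ratio 2.14

recovery_check(cfg, sim, n_boot = 300)
#> <recovery_report>
#>   events: 591 detected vs 533 true; hypo minutes: 19050 vs 19050
#>   minute risk ratio 2.14; onset rate ratio 2.50 (95% CI 2.12-2.87) vs configured 2.50
#>   <test_result> event_start_gof_chi2: statistic 106.2 (df 1), p = 6.75e-25 [192 of 591 starts inside (expected 98.6)]
```

Reading this: 4.0% of monitored time was hypoglycemic, concentrated in the
early hours (7.2% inside vs 3.3% outside the 03:00–07:00 window; 29.97% of
all hypoglycemic minutes in a window that covers 16.7% of the day). The
onset-rate-ratio estimator recovers the configured 2.5× hazard exactly,
while the minute-based risk ratio (2.14) is diluted by events spilling
across the window boundary — which is why the recovery check estimates the
hazard from event starts. Detected events (591) exceed true events (533)
only because 2% sensor dropout can split an event across the gap rule;
with `dropout_prob = 0` the counts match exactly.

`run_full_analysis()` wraps all of the above (plus exclusion intervals,
subgroup comparisons and the threshold sweep) and writes a deterministic
report bundle; `scripts/cgmtempo_run.R` exposes `simulate` and `run`
subcommands for shell use.

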