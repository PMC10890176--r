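# hypoval

Event-based forward validation of continuous hypotension-prediction
indices against invasive arterial-pressure recordings.

## The problem

Continuous prediction indices for arterial hypotension (0–100 scales
computed from the arterial waveform, such as the Hypotension Prediction
Index used in PACU/ICU monitoring) are validated not as per-sample
classifiers but as *alarms*: what matters clinically is whether an alert
precedes a hypotensive episode by enough time to act, and how often
alerts fire without an episode following. `hypoval` implements this
event-based "forward validation" methodology as a reusable, tested R
pipeline for anyone evaluating such an index against mean arterial
pressure (MAP) time series on a 20-second grid:

- **Hypotensive event**: MAP < 65 mmHg sustained ≥ 1 min (≥ 3
  consecutive 20-s samples); the event ends at the first MAP ≥ 65.
- **Alert** at threshold *t*: index > *t* sustained ≥ 1 min.
- **Forward scan**: each alert opens a 20-min prediction window. An
  event onset inside the window makes it a true positive (TP), with
  time-to-event (TTE) measured from alert to onset; otherwise it is a
  false positive (FP). Alert-free 20-min spans are negative predictions:
  false negative (FN) if an event onset falls inside, else true negative
  (TN). Windows are consumed as they are labeled, so each event and each
  negative span is counted exactly once.
- **Panel**: per threshold *t* ∈ {0, 5, …, 100}, sensitivity
  TP/(TP+FN), specificity TN/(TN+FP), PPV, NPV (Wilson 95% intervals),
  TTE median [IQR]; ROC curve over the sweep with trapezoidal AUROC; and
  the time-weighted average (TWA) depth of hypotension, the area under
  the 65 mmHg threshold divided by monitoring time (mmHg).

Artifact censoring (implausible MAP range, jump, flatline, missing
index) and a ≥ 3 h uninterrupted-data eligibility gate reproduce the
data hygiene such studies apply. Because patient recordings of this
kind are not generally public, the package ships a seeded synthetic
cohort generator (Ornstein–Uhlenbeck MAP baseline, injected smooth
hypotensive dips, several index behaviours from perfectly informed to
uninformative) with exact ground truth, so every pipeline stage is
testable without data.

## Worked example

```r
library(hypoval)

cfg <- synthetic_config(n_recordings = 8, duration_h = 6, event_rate = 1,
                        index_mode = "noisy", index_noise = 5, seed = 42)
cohort   <- generate_cohort(cfg)
censored <- lapply(cohort$recordings, censor_artifacts)
eligible <- eligibility_filter(censored)$eligible

sw <- threshold_sweep(eligible)
subset(as.data.frame(sw), threshold %in% c(0, 50, 85, 100),
       select = c(threshold, tp, tn, fp, fn, sensitivity, specificity,
                  ppv, npv, tte_median))
#>    threshold tp  tn  fp fn sensitivity specificity   ppv   npv tte_median
#> 1          0 47   0 102  0       1.000           0 0.315    NA        600
#> 11        50 47 103   0  0       1.000           1 1.000 1.000        200
#> 18        85 46 104   0  1       0.979           1 1.000 0.990        180
#> 21       100  0 110   0 47       0.000           1    NA 0.701         NA

roc_from_sweep(sw)
#> <hypoval_roc> 21 points, AUROC = 0.991

cohort_summary(eligible)
#> <hypoval_cohort_summary>
#>   8 recordings, 48.0 h monitored (8640 segments)
#>   47 hypotensive events, 116.0 min total
#>   events/patient 6 [4-8]; event duration 2.0 [1.7-2.8] min
#>   TWA 0.18 [0.13-0.34] mmHg
```

Reading the sweep: at threshold 0 every strictly positive index sample
alerts, so every event is predicted (sensitivity 1.00) and no negative
window exists (specificity 0.00); at threshold 100 a bounded index never
alerts, so the relationship inverts. In between, this noisy-but-informed
synthetic index predicts nearly every event with a ~3-minute median
warning, and the ROC over the 21 thresholds integrates to 0.991. The
`NA`s are undefined ratios (no alerts → no PPV), reported as absent
rather than zero. TTE at threshold 0 is long because with alerts firing
constantly, windows open far ahead of events.

`run_validation()` wraps the whole chain (file loading or generation,
censoring, gate, sweep, ROC, summary) and writes `sweep.tsv`,
`roc.json`, `cohort_summary.json`, `exclusions.tsv` and a `manifest.json`
sufficient to re-run bit-identically. A thin command-line wrapper lives
at `inst/cli/hypoval.R` (`generate` / `validate` subcommands).

Recordings load from delimited text with columns `time_s`, `map_mmhg`,
`hpi` (remappable via `dialect=`); see `?load_recording`.

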