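---
title: "Forward validation of hypotension-prediction indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward validation of hypotension-prediction indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoval)
```

## Why event-based validation

A continuous hypotension-prediction index emits a 0–100 value every 20
seconds alongside invasive mean arterial pressure (MAP). Scoring it
sample-by-sample against concurrent MAP would reward trivial
autocorrelation (MAP is already low when the index is high) and say
nothing about warning time. Event-based *forward validation* instead
asks the clinical question directly: when the index crosses an alert
threshold and stays there for a minute, does a hypotensive episode begin
within the next 20 minutes, and how far ahead of the onset did the alarm
fire?

All durations in the package are counted in whole 20-second segments;
sample $k$ owns the half-open interval $[t_0 + 20(k-1),\, t_0 + 20k)$
seconds. "At least one minute" therefore means at least 3 consecutive
samples.

## The labeling scan

Within one contiguous block of valid samples:

* **Events.** A hypotensive event is a maximal run of $\ge 3$ samples
  with MAP $< 65$ mmHg; it ends at the first sample with MAP $\ge 65$
  (or the block end). One- and two-sample dips are ignored as transient.
* **Alerts.** At threshold $t$, alerting is *active* at any sample
  inside a maximal run of $\ge 3$ samples with index strictly $> t$.
  The strict comparison makes threshold 100 alert-free for a bounded
  index and threshold 0 alert-everywhere for a strictly positive one —
  which is what pins the analytic endpoint rows of the sweep
  (sensitivity 1.00 / specificity 0.00 at threshold 0, and the reverse
  at 100).
* **Scan.** A single pointer moves forward through the block. At the
  earliest active alert within 20 minutes of the pointer, a 20-minute
  window opens at the *alert anchor* — the later of the exceedance-run
  start and the pointer, so an exceedance still in progress after a
  labeled window re-alerts immediately rather than being used up. If an
  event onset falls inside the window the label is TP with
  time-to-event = onset − anchor, and the pointer jumps to the event
  end; otherwise FP, and the pointer jumps to the window end. If no
  alert is active within 20 minutes of the pointer, that span is one
  negative prediction — FN if it contains an event onset (pointer to
  event end), else TN (pointer advances a full 20 minutes). A trailing
  partial span containing neither alert nor event is discarded.

This consumes time as it labels, so each event onset contributes to
exactly one label (TP or FN), no two positive windows overlap, and the
absence of hypotension is counted once per 20-minute span rather than
once per sample.

### Tie-breaks and degenerate cases

The scan needed three decisions the verbal description leaves open:

* **Anchor inside an ongoing event.** An exceedance that only begins
  after the event has started is not a prediction; such anchors are
  suppressed until the event ends. An anchor falling *exactly on* the
  onset, however, still predicts (TP with TTE 0): the alert and the
  event begin together, and suppressing it would manufacture false
  negatives at threshold 0 with a strictly positive index, where the
  endpoint identity sensitivity = 1.00 must hold analytically.
* **Anchor vs. onset tie at the pointer.** When the next anchor and the
  next onset coincide, the alert branch wins (TP), for the same reason.
* **Trailing partials.** A final span shorter than 20 minutes is
  labeled only if it contains an alert (TP/FP, window truncated by the
  block end) or an event (FN); otherwise it is dropped, avoiding
  asymmetric short negatives.

The whole scan is mirrored by a deliberately naive sample-by-sample
state machine in the test suite (no shared code); the two
implementations are compared element-wise on 200 seeded random
recordings at six thresholds.

## The outcome panel

For each threshold of the sweep (0 to 100 in steps of 5, pooled across
recordings) the package reports TP/TN/FP/FN counts, sensitivity,
specificity, PPV and NPV with 95% confidence intervals, and the TTE
median [IQR] over TP windows.

* **Intervals** are Wilson score intervals: stable at small counts,
  never outside $[0,1]$, always containing the point estimate. (The
  same interval is produced by `prop.test(..., correct = FALSE)`, which
  the tests use as a cross-check.)
* **Undefined ratios** (PPV with no alerts, TTE with no TPs) are
  reported as missing, never zero-filled.
* **Quantiles** use linear interpolation between order statistics (R
  type 7); the convention matters when reproducing a TTE IQR and is
  therefore fixed and documented.
* **ROC/AUROC**: one point $(1-\text{specificity}, \text{sensitivity})$
  per threshold with both ratios defined, plus anchors $(0,0)$ and
  $(1,1)$; AUROC by trapezoidal integration over FPR-sorted points,
  keeping the maximal TPR at a duplicated FPR. No binormal smoothing is
  applied — only the discrete sweep exists.
* **TWA of hypotension**: $\sum_k \max(0, 65 - \text{MAP}_k) \cdot 20
  \,/\, (20 n)$ mmHg over valid samples — area under the 65 mmHg
  threshold divided by monitored duration.

## Censoring and eligibility

Arterial-line recordings carry artifacts that would corrupt labeling:
line flushes and blood draws (spikes/steps), transducer disconnections
(flatlines). The default rule set masks samples with MAP outside
[20, 200] mmHg, |ΔMAP| > 30 mmHg between consecutive samples (both
samples), more than 15 identical consecutive MAP values (5 min), or a
missing index value. The thresholds are package defaults — chosen once
as conservative physiologic plausibility bounds, not fitted to anything
— and all are configurable. Censoring only ever clears the validity
mask; values are preserved, the operation is idempotent, and labeling
runs inside maximal contiguous valid blocks. Gaps are never
interpolated.

Cohort eligibility requires at least one *contiguous* valid block of 3
hours; the stricter contiguous reading (rather than cumulative valid
time) is deliberate, and the gate is applied at cohort assembly so unit
tests can use short traces.

## The synthetic cohort generator

No public recordings of this kind exist, so the generator emulates the
statistical structure such a cohort reports, with exact ground truth:

* **Baseline MAP**: an Ornstein–Uhlenbeck process (mean 80 mmHg,
  correlation time 300 s, stationary SD 4 mmHg) — the simplest
  stationary process with tunable autocorrelation — softly reflected at
  68 mmHg so spontaneous crossings of 65 never occur and every
  sub-threshold excursion is an injected, bookkept event.
* **Events**: Poisson-placed smooth dips. Defaults target the shape of
  a monitored PACU/ICU cohort: 11.3 h recordings, event rate 4/11.3 per
  hour (≈ 4 events per recording), log-normal durations with median
  120 s and quartiles near 1.5 and 2.7 min (sdlog 0.45), log-normal
  nadir depths with median 8 mmHg below 65. Dips are half-sine
  excursions whose 65-mmHg crossing times fall strictly *between* grid
  samples, so the number of sub-65 samples — and hence detectability —
  is controlled analytically, and detection recovers injected onsets to
  the sample. Durations drawn below 60 s are injected but undetectable
  by definition; configurations where that mass exceeds 25% trigger a
  warning.
* **Index modes**: `perfect` (100 from `lead_time` = 180 s before onset
  until event end, 0 elsewhere), `lagged` (logistic transform of the
  MAP deficit 180 s ahead — strictly inside (0, 100), which is what the
  threshold-0 endpoint checks require), `noisy` (lagged + Gaussian
  noise, clipped), and `random` (an AR(1) signal independent of MAP, on
  the same 300-s time scale as the MAP process).
* **Artifacts**: spikes (one sample at 230 mmHg), steps (+45 mmHg for
  six samples) and flatlines (20 identical samples), at a configurable
  hourly rate, placed clear of event neighbourhoods and recorded in the
  ground truth — exactly the three patterns the censor rules target.
* **Reproducibility**: each recording draws from a deterministic
  substream of the cohort seed, so cohorts are bit-identical across
  reruns (and would remain so under parallel generation); the global
  RNG state is restored afterwards.

What the generator does *not* emulate: waveform-level physiology,
treatment feedback (a vasopressor given at an alert would abort the
event), heavy-tailed between-patient event-rate heterogeneity, and any
particular real index's error structure. Passing tests on synthetic
cohorts therefore demonstrate the *labeling machinery* is correct and
calibrated, not that any real index performs well.

## A structural property worth knowing

With a *perfectly informed* index the pipeline behaves as expected:
every interior threshold gives sensitivity 1, specificity 1, AUROC
exactly 1.0, and TTE exactly the configured lead time. With an index
*independent* of MAP, however, the pooled AUROC does not settle at 0.5:
the acceptance suite measures ≈ 0.43 (30 recordings × 6 h, ~540 windows
per threshold). This is a property of the forward scan itself, not an
implementation artifact: labeled windows consume scan time, so the
effective alert-lookback available to an event averages only half a
window (~10 min), while the FP/TN decision always spans the full 20
minutes. An uninformative index thus has a lower chance of "covering"
an event than of contaminating a negative span, sensitivity falls below
the false-positive rate at matched thresholds, and the pooled ROC dips
below the diagonal. The effect shrinks as the index becomes more
persistent relative to the window and is irrelevant for genuinely
predictive indices, but it means a small AUROC deficit below 0.5 should
be read as "uninformative", not "anti-informative". Window-level PPV,
by contrast, does converge to window-level hypotension prevalence under
independence, as expected.

## Problem sizes

The test suite and acceptance script run on deliberately desk-scale
cohorts — recordings of 4–11.3 hours, cohorts of 6–30, differential
fixtures of 360 samples × 200 seeds — chosen so the full suite
completes in well under a minute while every property is exercised at
sample sizes where its failure modes are visible (hundreds of windows
per threshold, dozens of injected events).

## Known limitations

* The labeling operates on the 20-s grid only; finer-grained inputs are
  decimated (last value per bin) when the period divides 20 s exactly,
  and rejected otherwise rather than resampled.
* Only the single hypotension definition MAP < 65 mmHg sustained ≥ 1
  min is supported; multi-level definitions are out of scope.
* Censor rules are heuristics over MAP values alone; interventions that
  change hemodynamics smoothly (fluid boluses, vasopressors) are not
  detectable from the trace and are not masked.
* The index is treated as an opaque signal; nothing here computes or
  approximates any proprietary index.
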