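---
title: "Artifact correction and attention quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact correction and attention quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemend)
```

## The problem

Eye trackers used inside an MRI scanner record monocular gaze position at
1000 Hz over sessions lasting minutes. The raw sample stream contains three
artifact classes that corrupt any dwell-time analysis downstream: transient
spikes (millisecond excursions that snap back to the true trajectory),
spatial displacements (the recorded position is offset for tens to hundreds
of milliseconds while relative motion stays accurate), and blinks (runs of
null samples flanked by ~0.1 s sharp vertical excursions of the recorded
gaze as the eyelid progressively occludes the pupil). gazemend implements
detection and correction of all three, quantification of on-screen and
AOI-directed gaze under a block paradigm, and the nonparametric group
statistics appropriate for small cohorts and bounded, non-normal rate data.

## Geometry and the velocity threshold

All velocity thresholds are expressed in pixel units per millisecond. The
conversion from visual angle uses exact trigonometry at the screen center:
`px_per_degree = d · tan(1°) / pitch`, with `d` the viewing distance and
`pitch` the physical pixel size. We use a single screen-center conversion
for the global threshold rather than per-sample eccentricity-corrected
angles; across this screen the difference is well under 1% and the threshold
is a safety ceiling, not a precise boundary.

The default geometry is 1680 × 1050 px at 1 m. Physical panel size is rarely
reported with the data, so the default width (0.6604 m) is **back-derived**
so that the physiological saccade-speed ceiling of 0.9°/ms equals 40 px/ms
(nearest integer), the conventional threshold value in pixel units. Every
geometry field is config-overridable; `detector_config(geom = ...)` derives
the threshold from any other geometry.

## Detection

`compute_velocity()` uses the backward finite difference per axis divided by
the actual time step. Backward (not central) differences keep causality: a
correction at sample *i* never depends on later corrected values during
displacement reintegration. Velocity is undefined at the first sample and
wherever either neighbour is invalid.

Sensor artifacts are segmented on a blink-free trace by a two-part rule:

1. a sample whose speed exceeds the threshold opens an artifact (onset);
2. the onset is paired with the next super-threshold sample whose velocity
   vector has **negative dot product** with the onset velocity — the 2-D
   generalization of "the gaze jumps out, then jumps back the opposite way"
   — within a 500 ms pairing window.

Intervals no longer than `max_spike_ms` (default 10 ms) are transient
spikes, longer ones spatial displacements. The duration boundary is only
qualitatively constrained by the artifact phenomenology ("a few
milliseconds" versus "tens to hundreds"), so it is configurable; 10 ms
leaves an order of magnitude on each side at 1000 Hz. Onsets that never find
a return jump are flagged `unterminated` and left uncorrected rather than
guessed at. Because genuine saccades are sub-threshold by construction, no
separate fixation/saccade classifier is needed, and a trace with no
super-threshold sample yields no detections — there are no false alarms by
construction on clean data.

Blinks are detected as maximal runs of `valid = FALSE` samples; interval
bounds are the timestamps of the first and last invalid sample (closed
spans; sensor-artifact intervals are half-open `[onset, offset)` over the
velocity events, so a one-sample spike has positive duration).

## Correction

* **Spikes** (default `mode = "post"`) are overwritten with the first
  trusted sample at/after the interval end — the artifact returns to the
  correct trajectory, so the final moment's datum is correct. `pre` and
  `bridge` modes are provided because on slowly varying traces all three are
  equivalent to within one sample step.
* **Displacements** keep the within-interval first derivative (it is
  accurate) and fix only the level. The level is pinned by a symmetric
  boundary condition: the constant removed from the interval is the mean of
  the entry jump and the negated exit jump. This reduces to plain
  reintegration from the last pre-onset position on a steady base and is
  exact whenever the true motion during the entry and exit jumps is equal —
  including constant and linear-ramp trajectories, and any constant-offset
  artifact on them. A one-sided anchor (entry only) would instead carry a
  one-sample bias equal to the true step hidden under the entry jump; that
  step is unobservable, and splitting the residual equally is the estimate
  with the smallest worst-case error among level choices consistent with the
  trusted anchors on both sides.
* **Blinks** are deleted together with a `blink_pad_ms` pad (default 200 ms)
  on each side — subsuming the ~0.1 s flanking excursions — and refilled by
  per-axis linear interpolation between the nearest valid samples outside
  the padded window. Gaps touching a record boundary are filled by holding
  the nearest valid value; no extrapolation. Overlapping padded windows are
  merged before interpolation. Refilling (rather than excising) keeps the
  time base unbroken, which condition assignment requires.

`clean_recording()` runs blinks first, then velocity-based detection, then
spike and displacement correction in time order. Blink-first ordering is
essential: the flanking excursions would otherwise spawn spurious spike
detections. The pass preserves length and timestamps, leaves no invalid
samples, and is idempotent — a second pass detects nothing (verified
property-style over random injected traces).

## Quantification

Rates are sample-count fractions; at a uniform sampling rate, counts are
proportional to dwell time. The on-screen rate of a condition is the
fraction of its samples that are valid and inside `[0, width) × [0, height)`
(half-open, matching the screen's pixel index range); lost samples count
against the rate in both the raw and the filtered variant, which is what
lets interpolation legitimately raise the filtered rates. AOI rates use
half-open boxes, side-matched to each trial's target side for the object
conditions. The denominator is all samples of the condition, not just
on-screen ones, so task rates are directly comparable across variants.

Per-trial rates aggregate by repeated trial position: within-block position
1–5 for the multi-trial conditions (AJ, NOAJ), block occurrence 1–4 for the
single-trial Center blocks. The first-vs-last comparison on Center therefore
spans positions 1 and 4 under the default schedule. AOI geometry is
study-specific: the built-in `default_aois()` layout (200 × 200 px cross
box, 400 × 400 px object boxes at quarter-width positions) is a documented
placeholder, and real analyses should load their layout from a config.

## Group statistics

`wilcoxon_signed_rank()` drops zero differences (classic convention,
reported in the result), uses the exact signed-rank null for up to 25
untied pairs — so a 16-subject cohort takes the exact path — and otherwise a
normal approximation with tie-corrected variance and continuity correction.
The exact path is verified in the tests against full 2^n sign enumeration
for all n ≤ 12, and the approximation agrees with the exact p to better
than 0.01 at n = 20. `friedman()` delegates to the standard chi-square
Friedman test with average-rank ties (df = k − 1); fully tied data
(identical columns) are reported as statistic 0, p = 1 instead of the
indeterminate 0/0 form. `posthoc_pairs()` runs the signed-rank test on all
k(k−1)/2 column pairs with Bonferroni multiplication capped at 1. Missing
cells are refused, never imputed.

## The synthetic generator: what it emulates, and what it does not

The generator is the package's ground-truth source, built as the
constructive inverse of the artifact definitions:

* fixation traces: Gaussian jitter (default SD 1 px) around a target — at
  1000 Hz this produces velocity noise of ~1.4 px/ms, a factor ~28 below
  the threshold, so base traces never self-trigger detection;
* the two validation protocols: central fixation with ~1 blink/s (null runs
  of 150 ms flanked by 100 ms vertical excursions of 300 px, direction
  random per blink), and an Archimedean spiral scanned from the center
  outward at constant path speed (0.5 px/ms default), obtained by numerical
  inversion of the spiral's arc length so the chord speed never exceeds the
  nominal speed;
* artifact injection: spikes (1–3 samples, 200 px default amplitude, random
  direction), constant-offset displacements (150 px, 100 ms default) and
  blinks, placed uniformly at random with guard margins so corrections never
  interact, every interval recorded as truth;
* cohort sessions: gaze alternates between looks inside the trial's AOI and
  looks elsewhere on screen in 250 ms chunks, with per-chunk adherence
  probability `p = adherence[condition] − decay[condition] · (position − 1)`.
  Default adherence (Center 0.70, AJ 0.46, NOAJ 0.47) sits at the task-rate
  levels typical of this paradigm. Transitions between looks are ramped at
  32 px/ms — below threshold, as real saccades are — which means a fraction
  of a percent of samples lie between AOIs even at adherence 1; tests assert
  rates ≥ 0.99 rather than exactly 1 for that reason.

The generator does **not** model main-sequence saccade dynamics, smooth
pursuit gain, pupil-size foreshortening, head motion, or calibration drift.
Artifact amplitudes and duration distributions are stylized (constant within
an injection) rather than device-measured. Passing the validation batteries
therefore establishes that the pipeline recovers artifacts *of the defined
classes* under realistic noise; it does not certify behaviour on artifact
morphologies outside the taxonomy.

## Numerical choices and degenerate inputs

* Intervals: half-open `[start, end)` everywhere in the paradigm and for
  sensor artifacts; blink spans closed over the invalid samples. Samples on
  block boundaries belong to the later block.
* Missing data are a validity mask, never sentinel coordinates — (0, 0) is a
  legal corner position. CSV empty cells, `NA`/`NaN` tokens and the
  EyeLink-ASC `.` token all normalize to `valid = FALSE`; tracker event
  lines are ignored and classification is recomputed, never trusted.
* Non-uniform timestamps are tolerated; velocity always divides by the
  actual time step.
* Zero valid samples, intervals touching both record boundaries, and
  unterminated displacements are uncorrectable and reported as such, with
  partial results where the pipeline can continue.
* All generators are seeded and restore the caller's RNG state; identical
  seeds give bit-identical outputs.

## Problem sizes in the validation batteries

The test batteries scale the study design to sizes chosen for tight,
repeatable statistics: artifact recovery runs 100 seeded injections on 60 s
fixation traces at 1000 Hz (precision/recall ≥ 0.95 per artifact class;
cleaned-vs-truth RMSE ≤ 0.2 of dirty-vs-truth); the group battery uses
16-subject cohorts — at 250 Hz for the original-vs-filtered Wilcoxon
direction check and at 50 Hz for the 100-replicate Friedman power (decay
0.15/trial, ≥ 80% detection) and type-I (zero decay, rejection ≤ 0.12)
simulations. Rates are sampling-rate-invariant (a tested property), so the
reduced-rate cohorts measure the same quantities at a fraction of the cost.

## Known limitations

* The displacement level is identifiable only up to the true motion hidden
  under the entry/exit jumps; the symmetric boundary condition is exact for
  equal hidden steps and biased by half their difference otherwise.
* The opposite-direction pairing assumes the return jump is the next
  super-threshold event; two overlapping artifacts inside one pairing window
  would be fused.
* Blink padding is fixed (default 200 ms), not adapted to the measured
  excursion extent.
* Group tables from real cohorts are not reproduced numerically: participant
  recordings are not distributed with the package, so group-level claims are
  validated in direction and statistical behaviour on synthetic cohorts
  only.
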