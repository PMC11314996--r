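# gazemend

Post-processing for high-rate eye-tracking recordings acquired during
block-design cognitive tasks (typically simultaneously with fMRI, where the
long acquisition and the scanner environment make sensor artifacts common).

Raw 1000 Hz monocular gaze data contain three characteristic artifact
classes:

* **transient spikes** — the recorded gaze jumps away from the true
  trajectory for a few milliseconds and snaps back;
* **spatial displacements** — the recorded position shifts to an offset
  location for tens to hundreds of milliseconds while the *relative* motion
  stays accurate, then returns;
* **blink artifacts** — runs of null samples while the eye is closed, flanked
  by ~0.1 s sharp vertical excursions as the lid occludes the pupil.

gazemend detects the two sensor artifacts with a velocity threshold set at
the physiological ceiling of saccade speed — 0.9°/ms, i.e. 40 px/ms under
the default screen geometry (1680 × 1050 px viewed at 1 m) — pairing each
super-threshold onset with the next super-threshold sample whose velocity
vector points the opposite way (negative dot product). Genuine saccades are
slower than the threshold by definition, so anything faster is sensor error.
Corrections follow the artifact physics: spikes are overwritten with the
first trusted post-interval sample, displacements are re-levelled by
reintegrating the (accurate) within-interval first derivative, and blinks
are deleted with a 0.2 s pad on each side and refilled by linear
interpolation. The package also quantifies on-screen and area-of-interest
(AOI) gaze rates per condition and trial under a block paradigm
(25 s AJ / 25 s NOAJ / 20 s cross, 4 repetitions, 280 s), and runs the
matching nonparametric group statistics: paired Wilcoxon signed-rank
(original vs filtered), Friedman across trial positions, and
Bonferroni-corrected post hoc pairs. A seeded synthetic-gaze generator with
injected ground-truth artifacts validates every stage.

Intended users: labs post-processing tracker exports (CSV or EyeLink-ASC
sample lines) from block-design experiments, and methodologists who need a
ground-truthed testbed for artifact-correction pipelines.

## Worked example

Simulate the 20 s continuous-blinking validation protocol (a subject
fixating the screen center while blinking about once per second), clean it,
and compare with the ground truth:

```r
library(gazemend)

geom <- screen_geometry()
geom
#> Screen geometry: 1680 x 1050 px, 0.6604 x 0.4128 m, viewed at 1.000 m
#>   44.40 px/deg at center; angular extent 36.5 x 23.3 deg

bt <- generate_blink_protocol(duration_ms = 20000, seed = 42)
bt
#> Injection truth (seed 42): 20000 samples, 20 artifact(s) [blink=20]

res <- clean_recording(bt$dirty)
res$report
#> Clean report: 0 spike(s), 0 displacement(s), 20 blink(s); 0 sample(s)
#> replaced, 11000 interpolated, 0 unterminated

rmse_recordings(res$recording, bt$clean)
#> [1] 0
```

All 20 blinks are found from their null runs; each one is deleted together
with a 200 ms pad on either side (20 × 550 ms × 1000 Hz = 11,000 samples)
and refilled by interpolation, recovering the noise-free fixation exactly
(RMSE 0 px). The default session schedule reproduces the block paradigm:

```r
build_default_schedule()
#> Block schedule: 12 blocks, 44 trials, 280 s total
#>   blocks per condition: AJ=4, Center=4, NOAJ=4
```

A thin command-line wrapper covers the end-to-end workflow
(`simulate → clean → quantify → stats → qc-report`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gazemend", package = "gazemend"))')
Rscript $CLI simulate --protocol blink --out run1 --seed 7
Rscript $CLI clean --in run1/blink_protocol_samples.csv \
    --out run1/cleaned.csv --report run1/report.json
```

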