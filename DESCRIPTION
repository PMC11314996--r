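Package: gazemend
Title: Artifact Correction and Attention Quantification for High-Rate Eye-Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for sample-level monocular eye-tracking
    recordings acquired at high sampling rates (e.g. 1000 Hz) during
    block-design cognitive tasks. Detects and corrects three artifact
    classes -- transient spikes, spatial displacements, and blink-related
    data loss -- using a saccade-speed velocity threshold and an
    opposite-direction pairing rule; quantifies on-screen and
    area-of-interest (AOI) gaze rates per condition and trial under a block
    paradigm; and runs the matching nonparametric group statistics
    (Wilcoxon signed-rank, Friedman, Bonferroni-corrected post hoc pairs).
    A seeded synthetic-gaze generator with injected ground-truth artifacts
    supports validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
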