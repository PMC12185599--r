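Package: seegerd
Title: Beta-Band Desynchronization Analysis for Stereo-EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for detecting event-related
    desynchronization (ERD) in intracranial stereo-EEG (SEEG) depth-electrode
    recordings collected during delayed-reach tasks. Provides a seeded
    synthetic SEEG cohort generator with known ground truth; task and
    trial-selection modelling with per-phase analysis windows and behavioral
    summaries; preprocessing including drift-tolerant line-noise removal,
    fixed-threshold interictal spike detection, and RMS-weighted electrode
    shaft re-referencing; multitaper power spectral density estimation with
    bootstrap confidence intervals and interquartile-range outlier rejection;
    and frequency-cluster permutation tests of between-phase band-power
    contrasts with cohort-level modulation and laterality summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
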