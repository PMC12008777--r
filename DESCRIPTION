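Package: tapbeta
Title: Sensorimotor Synchronization Analysis of Finger Tapping and Movement-Locked Beta-Band EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for cued finger-tapping
    (sensorimotor synchronization) experiments. Builds deterministic cue
    schedules for a 2x2x2 design (cue frequency, modality, rhythmicity),
    detects finger taps from 3-axis accelerometry with a sliding-window
    peak algorithm, computes behavioural synchronization metrics
    (inter-tap-interval discrepancy and variability, circular tap phases,
    resultant vectors, circular medians) and circular hypothesis tests
    (Rayleigh, Rao spacing, Watson goodness of fit, Moore paired test),
    performs Morlet-wavelet time-frequency analysis of beta-band (12-30 Hz)
    EEG with spherical-spline surface Laplacian referencing, decibel
    baseline normalization and tap-locked window averaging, and fits
    hierarchical Bayesian factorial models with a Gibbs sampler to contrast
    cue conditions via 99% highest-density intervals. Includes a
    ground-truthed synthetic-data generator (tap trains, accelerometer
    transients, 1/f EEG with planted beta-band envelopes) so every stage is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
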