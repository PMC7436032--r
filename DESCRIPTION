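Package: armswing
Title: Wrist-Accelerometer Arm Swing Analysis for Parkinsonian Gait
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and group statistics for dual-accelerometer
    wristband recordings of arm swing during walking, aimed at quantifying
    motor asymmetry in Parkinson's disease. Implements four complementary
    techniques: root-mean-square angular acceleration with an arctangent
    arm swing asymmetry (ASA) index, unbiased autocorrelation regularity of
    the swing cycle and its posterior-anterior half-phase, FFT band energies
    separating locomotor (0-2.5 Hz) from tremor (5-10 Hz) content, and a
    wavelet-variance fractal dimension per axis. Arms are relabeled to the
    less/most affected side before nonparametric group comparison
    (Shapiro-Wilk gated Mann-Whitney U or Z test with Cohen's d). A seeded
    two-arm gait simulator generates synthetic cohorts with controllable
    amplitude asymmetry, half-phase asymmetry, tremor, and 1/f^beta noise so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
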