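Package: mdatsim
Title: Single-Sensor EMG Magnitude-Discretization Training: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless re-implementation of a single-channel surface-EMG
    magnitude-discretization control scheme and the gamified Muscular
    Discretization Assessment Tool (MDAT) built on it. Provides the signal
    conditioning chain (rectification, high-pass filtering, envelope
    smoothing, quantization to the 0-1023 device scale), a resting-baseline
    gated contraction ("flex") detector, discretization zones with
    calibration, a cue-based trial engine with static and progressive cohort
    schedules, synthetic EMG and survey generators for simulated
    participants, SUS / NASA-TLX / Edinburgh Handedness scoring, and the
    cohort statistics pipeline (paired and Welch t tests with Cohen d,
    Hedges g and d_av, Kruskal-Wallis, Spearman, Mann-Whitney with
    rank-biserial r).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
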