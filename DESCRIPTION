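Package: socoupling
Title: Individualized Slow-Oscillation/Spindle Coupling Analysis for Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for event-locked cross-frequency coupling between
    slow oscillations and sleep spindles in polysomnography recordings.
    Separates the 1/f fractal background from true oscillatory activity by
    irregular-resampling auto-spectral analysis (IRASA), parameterizes
    individual slow-oscillation and spindle frequency peaks, detects events
    with individualized percentile-threshold algorithms, quantifies
    slow-oscillation phase at spindle peaks with circular statistics
    (preferred phase, phase-locking value, bootstrap controls), and provides
    group-level inference (cluster-based permutation tests, rank and circular
    correlation families, percentile bootstrap comparison of dependent
    correlations).  A synthetic polysomnography generator with full ground
    truth (fractal background, injected events, von Mises phase coupling,
    paired longitudinal cohorts with behavior) supports validation of every
    stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
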