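Package: replaykit
Title: Hippocampal Replay Analysis with Ground-Truth Synthetic Sessions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal place-cell recordings during
    spatial learning: trial segmentation and learning-point detection, rate
    maps and place-field classification (stable, context-dependent, appearing,
    disappearing), memoryless Bayesian position decoding with leave-one-out
    validation, theta-sequence quadrant scores, sharp-wave-ripple and
    synchronous-event detection, replay content (representation rates) and
    directionality (weighted correlation, sequence score) analysis, and
    hierarchical Bayesian event-rate and proportion models fit by MCMC.
    Includes a synthetic-session generator (lattice maze, phase-dependent
    trajectories, theta-modulated Poisson place cells with phase precession,
    LFP with embedded ripples and time-compressed replays) that provides
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
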