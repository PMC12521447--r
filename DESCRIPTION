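Package: ldaepr
Title: Loudness Dependence of Auditory Evoked Potentials: Simulation,
    Preprocessing and Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for the loudness dependence
    of auditory evoked potentials (LDAEP), an electrophysiological index of
    central serotonergic activity. Simulates multichannel auditory-evoked EEG
    cohorts with known ground-truth N1/P2 intensity slopes, cleans raw
    recordings with an automated artifact pipeline (average re-referencing,
    resampling, spectral line-noise interpolation, bad-channel and bad-segment
    detection, EOG regression, epoching, statistical epoch rejection), extracts
    N1/P2/N1P2 peak amplitudes at Cz across five tone intensities and fits
    per-subject LDAEP slopes, and runs the group-level inferential layer
    (one-way ANOVA, Type II ANCOVA with partial eta squared and estimated
    marginal means, rank and exact tests, effect sizes, and noncentral-t power
    analysis).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    car,
    emmeans,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
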