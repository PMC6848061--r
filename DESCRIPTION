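Package: vsdmap
Title: Voltage-Sensitive Dye Imaging of Evoked Cortical Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of stimulus-locked voltage-sensitive dye (VSD)
    fluorescence movies of rodent cortex: blank subtraction for dye-bleaching
    removal, trial averaging, per-pixel fractional fluorescence change
    (dF/F), 9x9 spatial smoothing, detection of significant evoked
    excitation by a 7x baseline-noise-SD rule with initial-response,
    maximum-response and peak-amplitude descriptors, landmark-based rigid
    alignment across animals with majority (>=50%) overlap maps, von Frey
    head-withdrawal threshold determination, and pooled two-sample
    Student's t statistics with Bonferroni-family labelling, computable
    from raw values or from printed summary statistics. A seeded synthetic
    cohort generator emulates the acquisition (bleaching, sensor noise,
    alpha-kernel evoked transients, landmark displacement, behavioural
    sessions) so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
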