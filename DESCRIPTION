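Package: smeloc
Title: Simulation and Source Localization of ERP Subsequent Memory Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for studying subsequent source-memory
    effects in developmental EEG at desk scale. Generates synthetic
    multi-subject epoched EEG with planted P2 and late-slow-wave (LSW)
    sources in medial-temporal and fMRI-informed cortical patches;
    computes an analytic multi-layer concentric-sphere forward model and
    fiducial-based montage alignment; preprocesses and scores scalp ERP
    components with a 2x3x3 repeated-measures ANOVA and Tukey-corrected
    estimated-marginal-means contrasts; reconstructs current density with
    an eLORETA inverse operator and scores region-of-interest (ROI)
    activity; and tests group-level condition contrasts with paired
    t-tests under Benjamini-Hochberg false-discovery-rate control applied
    separately per hemisphere and mask family.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
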