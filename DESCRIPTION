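Package: icaffect
Title: Source-Space EEG Emotion Regression via Independent Component
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating EEG independent components whose
    frequency band power tracks emotional state.  Implements a complete
    source-space analysis chain: FIR band-pass filtering and epoch
    cleaning, independent component analysis with equivalent current
    dipole localization in a spherical head model, cross-participant
    k-means clustering of dipolar components, Welch band-power feature
    extraction, emotional-state-specific leave-one-participant-out
    regression of valence and arousal ratings, and Fisher-z group
    inference with Holm-Bonferroni correction.  A synthetic cohort
    generator plants known rating-to-band-power effects in dipolar
    cortical sources so that every stage of the chain can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
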