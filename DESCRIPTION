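Package: cortilick
Title: Analysis of Cortical Calcium Imaging and Licking Behavior in Head-Fixed Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of an analysis chain for
    head-fixed mouse sensorimotor experiments: two-photon calcium trace
    conditioning (neuropil correction and mode-based z-scoring in 100-s
    blocks), event-aligned response statistics and population PCA
    trajectories, a probabilistic-population-code decoder of lick direction,
    facial-video jaw-movement quantification, wide-field delta-F/F cortical
    mapping with early/late response localization, and optogenetic motor-map
    centroiding.  A seeded synthetic-data generator emulates the trial
    structure and signal statistics of such experiments (block-structured
    multimotor sessions, multisensory detection sessions, direction-tuned
    calcium transients with neuropil contamination, small preparatory jaw
    movements, two-spot wide-field activations) so that every analysis stage
    carries a ground-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
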