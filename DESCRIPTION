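Package: flyoperant
Title: Operant Self-Administration Arena Analysis for Individual Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for single-fly operant self-administration
    sessions in a two-zone oblong arena: centroid tracking from infrared
    frame stacks, per-frame region occupancy and time-binned occupation
    scores, entry-to-exit bout segmentation, session and bout behavioral
    metrics, preference and operant-learning indices, occupancy heat-map
    matrices, a PCA valence summary, forced-choice T-maze indices, and a
    valence-parameterized semi-Markov locomotion simulator that generates
    synthetic sessions (and rendered frames) with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
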