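Package: fitland
Title: Fitness Landscape Modeling and Machine-Learning-Guided Protein Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for supervised protein sequence-function modeling and
    model-guided sequence design. Provides linear, fully connected,
    sequence-convolutional and structure-graph-convolutional fitness
    predictors with ensemble (median and conservative percentile)
    aggregation; a synthetic epistatic fitness-landscape simulator with
    local single/double-mutant and combinatorial sampling plus sort-seq
    count generation; a fixed-mutation-distance simulated-annealing design
    engine with K-means representative selection; extrapolation metrics
    (mutation-count-stratified rank correlation, recall at a design budget,
    ensemble divergence along mutational trajectories); and sort-seq
    enrichment scoring from sorted-population read counts, including
    read-pair merging, exact-match counting, quadrant classification and
    Hill-equation titration fits.
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
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
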