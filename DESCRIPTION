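Package: bruxmorph
Title: Morphology-Based Genetic Group Prediction for Brettanomyces bruxellensis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking cell morphology of the wine spoilage yeast
    Brettanomyces bruxellensis to its four microsatellite-defined genetic
    groups. Provides a ground-truthed synthetic brightfield micrograph
    generator with group-specific morphology (length/width ratio, area,
    budding, multicellular aggregates), quantitative morphometry by
    segmentation or ground truth, a tile-balance-split-augment pipeline for
    224x224 thumbnails, a compact convolutional network trained from scratch
    with majority-vote image-level assignment, a full classification metric
    panel, and a RAPD-PCR profile / genetic-group concordance checker.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
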