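Package: iridetect
Title: Genome-Based Prediction of Structural Color in Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict structural color (SC) of bacterial colonies from
    genome content. Implements a pan-genome association workflow linking
    ortholog presence/absence to a binary colony phenotype (Fisher exact test
    with Bonferroni correction, label-permutation test, and a tree-aware
    contrasting-pairs test), profile hidden Markov models built from protein
    family alignments for presence/absence feature extraction, a random-forest
    classifier with out-of-bag error and Gini importances, empirically derived
    score bands for classifying genomes and metagenomes, ecological survey
    summaries (biome aggregation, score-depth correlation, bimodality valley
    detection), and grating-equation analysis of angle-resolved colony
    reflectance spectra. Seeded synthetic-data generators emulate every input
    so the full pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
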