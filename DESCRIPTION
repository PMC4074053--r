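Package: endoscreen
Title: Distribution-Shape Statistics and Parsimony Trees for High-Content
    Endocytosis Screens
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for image-based RNAi screens of endocytic
    activity measured at single-cell resolution on printed cell arrays.
    Provides a seeded synthetic-screen generator with known ground truth;
    extraction of 27 per-cell intensity and morphology features from
    multi-channel images via multi-radius top-hat background subtraction;
    a modified two-sample Kolmogorov-Smirnov Z-score that detects changes
    in the shape of per-well single-cell feature distributions against
    in-slide negative controls; replicate-consistent hit calling with
    permutation null curves; maximum-parsimony clustering of binary
    perturbation profiles over the feature set with jackknife consensus
    support, gain/loss event assignment and Gene Ontology term pull-up;
    hypergeometric and permutation-based network enrichment of tree nodes;
    and quadrant classification of pulse-chase secondary assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
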