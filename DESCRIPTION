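Package: catwarp
Title: Category-Structure Memory Warping: Stimuli, Schedules, and a
    Two-Pathway Hippocampal Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how category structure warps memory for object
    features. Builds two-category "satellite" stimulus sets with shared and
    unique parts, assigns part colors on circles in a CIELAB plane and derives
    attract/repel/orthogonal foils, generates constraint-satisfying trial
    schedules for exposure, interleaved part-learning/color-memory blocks, and
    a post-learning test, and simulates C-HORSE, a rate-coded two-pathway
    autoencoder model of the hippocampus (entorhinal cortex, dentate gyrus,
    CA3, CA1) trained with Contrastive Hebbian Learning on the same category
    structure. Includes feature-level representational similarity analysis
    with Fisher-Z averaging, multidimensional scaling of hidden-layer
    representations, pathway-lesion contrasts, a synthetic-participant
    generator for five-alternative color-memory choices, and the behavioral
    attraction-bias analyses (bias scores, foil-choice profiles, accuracies,
    classical tests, and power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
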