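Package: surfcrf
Title: Pairwise Conditional Random Fields for Enhancing Protein Interface
    Predictions on the Protein Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the surface of a protein chain as a pairwise conditional
    random field (pCRF) over the spatial neighborhood graph of its surface
    residues and uses it to re-label residues scored by any residue-wise
    protein-protein interface predictor. Provides neighborhood-graph and
    interface-label construction from PDB structures under three data-set
    conventions, binned score features with weighted node and edge potentials,
    exact and beam-pruned MAP decoding by a generalized Viterbi algorithm on
    arbitrary graphs, a log-domain forward pass with posterior sampling and
    marginals, piecewise training with class-imbalance amplifiers, a
    beta-distributed score simulator with spherical synthetic surfaces, and an
    evaluation harness (kappa-scaled ROC/AUC, Surface AUC Ratio,
    matched-specificity comparison, enhance-above-theta, k-fold
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
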