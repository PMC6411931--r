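Package: rbpforest
Title: RNA-Binding Protein Target Prediction with PWM Features and Random Forests
Version: 0.1.0
Authors@R:
    person("rbpforest", "developers", email = "rbpforest@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a human RNA-binding protein (RBP) binds a given
    RNA sequence from its position weight matrix (PWM). Each candidate
    sequence is scanned for the ten best PWM matches and encoded into a
    40-feature vector (matching, clustering, structural accessibility via
    constrained folding, and evolutionary conservation). Per-RBP "specific"
    random-forest classifiers are trained on raw features; a pooled "general"
    classifier is trained on features z-standardized against a background
    sequence set so that RBPs with few or no known targets can be scored.
    Includes a deterministic random-forest implementation with out-of-bag
    evaluation and permutation importance, a Nussinov-style internal folding
    backend plus an adapter for an external folding program, AUC/AUPRC
    evaluation, seeded synthetic-data generators for end-to-end testing, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
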