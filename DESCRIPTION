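Package: gapnet
Title: Predicting Binary Phenotypes from Alignment Gap Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a binary phenotype across species from the pattern of
    gaps in a multi-species sequence alignment. Alignments are one-hot
    encoded (gap/nucleotide), reduced by principal component analysis, and
    optionally augmented with clade-membership features from a rooted species
    tree; an elastic-net-penalized dense feed-forward classifier is selected
    by cross-validation over a hyperparameter grid. Per-position predictive
    importance is assessed by reconstructing position-level coefficients from
    the principal-component weights and testing them with Hotelling's
    T-squared statistic under Benjamini-Hochberg adjustment. Includes a
    genome-scan mode that screens many regions for candidate associations,
    and a phylogenetic simulator (multispecies-coalescent gene trees, GTR+F
    sequence evolution with indels, Markov binary traits, lineage-specific
    whole-sequence deletion) for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
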