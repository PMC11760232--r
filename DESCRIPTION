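Package: sparseclade
Title: Evolutionary Sparse Learning for Phylogenetic Hypotheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparse group lasso logistic regression models that relate
    a phylogenetic hypothesis (membership in a focal clade, or any binary
    trait) to one-hot encoded multiple sequence alignments. Provides clade
    extraction from rooted Newick trees, four class-balancing strategies
    including a phylogeny-aware one, alignment encoding and feature
    filtering, an accelerated proximal-gradient solver with the closed-form
    sparse group lasso proximal operator, and post-processing into position,
    group and hypothesis sparsity scores, species prediction probabilities,
    cross-validation, regularization-path grid search, and a per-gene
    contribution matrix for diagnosing fragile clades.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
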