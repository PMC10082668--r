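Package: flexms
Title: Local-Alignment Phylogenetic Beta-Diversity for Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Marker-restricted ("local alignment") phylogenetic beta-diversity
    distances for microbial community profiles. Exact markers are selected by
    rank tests (or supplied by the user), approximate markers are recruited
    from a precomputed neighbor index combining sequence similarity, taxonomy
    and hierarchical functional distance, and their abundances are weighted by
    similarity to the nearest exact marker. Pairwise distances are computed by
    a branch-length-attenuated consistency-score recursion over a rooted
    phylogeny, alongside the whole-community global variant. Includes PCoA,
    PERMANOVA, ANOSIM, multivariate dispersion tests, leave-one-out KNN
    classification with ROC/AUC, and a synthetic two-group community generator
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    pROC,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
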