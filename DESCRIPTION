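Package: brdti
Title: Multi-Label Learning for Drug-Target Interaction Prediction and
    Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats each drug as a class label and its experimentally
    observed target genes as class-specific training data, turning
    drug-target interaction prediction into a multi-label learning
    problem. Genes are encoded as binary presence/absence vectors over
    Gene Ontology terms; a binary-relevance ensemble of l2-regularized
    logistic models (one per drug) predicts the drug label set of a
    gene. Includes iterative stratified multi-label k-fold
    cross-validation, per-instance hit/novel/Jaccard rates with
    thresholded aggregates, macro- and micro-averaged F-measures, DTI
    recall, extraction of novel drug-gene associations, drug-phenotype
    association via gene-phenotype maps, and a synthetic corpus
    generator with planted label signatures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
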