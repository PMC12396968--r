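Package: immunatlas
Title: Cross-Tissue Immune-Cell Atlas Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tested building blocks for multi-donor, multi-tissue CITE-seq
    immune atlas analysis: composite per-cell quality scoring with
    cluster-level filtering, pseudobulk differential expression with
    composition-versus-expression disentanglement, consensus Poisson matrix
    factorization with tissue- and age-factor selection, counterfactual
    per-cell effect-module discovery, compositional shift testing, ADT
    landmark registration and percent-positivity analysis, and TCR/BCR
    repertoire clonality. Ships a synthetic-data generator with planted
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    limma,
    edgeR,
    lme4,
    lmerTest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
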