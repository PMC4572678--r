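Package: apkl
Title: Hybrid Gene Selection with Affinity Propagation and the
    Krzanowski-Lai Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete two-class gene-expression analysis toolkit built
    around a hybrid gene-selection method: genes are ranked by
    Westfall-Young maxT permutation-adjusted significance, the number of
    clusters among the top-ranked genes is estimated with the
    Krzanowski-Lai index, affinity propagation partitions those genes
    into that many clusters, and one exemplar per cluster is returned as
    the gene signature. Supporting modules cover tab-delimited data
    import, seeded stratified train/validation sampling, nine
    normalization/transformation variants, SVM-based classification
    assessment (AUC, MCC, accuracy, sensitivity, specificity),
    mutual-information network reconstruction (CLR and ARACNE pruning)
    with weighted centralities and hub detection, table-driven probe and
    pathway annotation, HTML report generation, and a synthetic-data
    generator with planted differentially expressed gene clusters for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
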