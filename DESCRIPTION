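Package: mircons
Title: Consensus-Based Inference of miRNA-miRNA Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds disease-specific miRNA expression matrices from curated
    fold-change records, scores every miRNA-disease node pair with six
    network-inference algorithms (Pearson and Spearman correlation, distance
    correlation, the mutual-information methods CLR and MRNETB, and a
    randomized tree-ensemble method), fuses the per-algorithm rankings into a
    single confidence score per interaction by Borda-count consensus,
    validates predictions against a PubMed co-citation truth network with
    precision-recall and ROC analysis, and mines miRNA-miRNA signature
    components conserved across the diseases of a class by graph
    intersection. Includes a synthetic record generator with planted
    correlated miRNA modules for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
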