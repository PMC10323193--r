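Package: crossboruta
Title: qPCR Array Fold-Regulation Statistics and CrossBoruta Gene
    Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for threshold-cycle (Ct) data from
    pathway-focused qPCR arrays, built around a four-group rat cardiac
    graft ischemia/reperfusion design. Implements delta-Ct reference-gene
    normalization, fold change and fold regulation with Student's t-tests
    and significance/QC filtering; an all-relevant Boruta feature
    selector (shadow features, randomized-forest importance, binomial hit
    testing) iterated over every gene as target to assemble CrossBoruta
    gene-gene interaction networks with Spearman-signed edges; stress
    majorization (SMACOF) network layout; gain-ratio (C4.5-style)
    decision-tree induction for inter-group classification; and a seeded
    synthetic Ct-matrix generator with planted differential expression
    and correlation modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
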