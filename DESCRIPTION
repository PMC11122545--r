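Package: uskit
Title: Mucosal qPCR Markers of Ustekinumab Response in Ulcerative Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of mucosal gene-expression markers of ustekinumab
    response in ulcerative colitis from threshold-cycle (Ct) data of an
    84-gene inflammation qPCR array. Implements the delta-delta-Ct
    differential expression analysis with housekeeping normalization and
    fold-regulation reporting, normality-gated Spearman co-expression
    networks with degree and betweenness centrality ranking of hub and
    bottleneck genes, supervised response classification with per-algorithm
    AUC and consensus feature importance, and clinical baseline-table
    statistics. A synthetic Ct-level cohort generator with planted fold
    regulations and latent-factor co-expression modules makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    tools,
    utils,
    igraph,
    glmnet,
    ranger,
    randomForest,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
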