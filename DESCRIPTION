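Package: mirffl
Title: Meta-Analysis of Differential Expression and miRNA Feed-Forward-Loop
    Network Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a multi-stage
    transcriptomic network pipeline: two-study differential-expression
    meta-analysis (per-study t or moderated t, Fisher sum-of-logs combination,
    Benjamini-Hochberg correction, fold-change screen), gene-set
    over-representation against GMT libraries, evidence-filtered
    protein-protein-interaction networks with five-centrality hub-gene calling
    (degree, betweenness, closeness, stress, edge-percolated component), and
    mining of 3-node miRNA-TF-gene feed-forward loops from typed regulatory
    edge tables with a human-mouse conservation filter and merged-network
    topology statistics. A synthetic-data module generates every input with
    known ground truth so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
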