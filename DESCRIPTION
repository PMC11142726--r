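Package: grnlink
Title: Supervised Gene Regulatory Network Inference by Graph Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed transcription-factor to target-gene regulatory
    edges from single-cell RNA-seq expression matrices by casting network
    inference as supervised link prediction. Gene nodes are embedded with
    GraphSAGE-style neighborhood aggregation, globally influential genes are
    selected by differentiable Top-k pooling, and each candidate edge is
    scored by a stacked convolutional classifier trained with binary
    cross-entropy. Includes BEELINE-style expression and reference-network
    readers, leakage-safe k-fold cross-validation with AUROC/AUPRC reporting,
    a planted-network synthetic data generator for desk-scale validation, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
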