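Package: vbctrace
Title: Viral Barcode Lineage Tracing and Monosynaptic Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of barcoded rabies virus experiments read out by
    sequencing. Implements UMI-based error correction of 20-bp viral
    genomic barcodes (VBCs) by abundance-ordered Hamming-family collapse,
    viral library diversity analytics (downsampling, abundance groups,
    unique-barcode draw curves), per-cell barcode cleaning for single-cell
    RNA-seq (mutational and bipartite UMI-sharing collapse), transcriptional
    starter-cell identification by dual binomial tests with iterative
    background-rate estimation, statistical filtering of barcodes to
    unitary clonal infectivity paths using birthday-collision founder
    statistics, monosynaptic network assembly, and downstream network and
    expression statistics. Ships a forward simulator of complete barcoded
    experiments with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
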