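Package: shmseq
Title: Spatial Host-Microbiome Sequencing Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for spatially resolved host-microbiome sequencing data:
    simulation of spatially barcoded 16S rRNA reads anchored at a surface-probe
    capture site, two-stage taxonomic classification (exact k-mer
    lowest-common-ancestor assignment with a convolutional/recurrent neural
    network fallback), spatial read processing (barcode demultiplexing, UMI
    collapsing) into taxa-by-barcode count matrices, a hierarchical
    zero-inflated Poisson spatial model with a conditional autoregressive
    smoothing prior fitted by Hamiltonian Monte Carlo, Savage-Dickey Bayes
    factor tests, and downstream spatial co-expression module and cell-type
    niche analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
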