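Package: perimir
Title: Quantitative Analysis of Perilesional miR-124-3p Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for studying chronic microRNA downregulation in
    perilesional cortex: per-cell quantification of chromogenic in situ
    hybridization signal over lesion-adjacent sectors, relative qPCR
    quantification by the 2^-ddCt method with Grubbs outlier screening,
    canonical miRNA seed-site scanning of 3'UTRs with differential-expression
    overlap, preranked gene set enrichment, and miRNA:target duplex
    minimum-free-energy prediction by dynamic programming. Ships a synthetic
    data generator that emulates the statistical structure of all inputs so
    every stage can be exercised and validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings,
    EBImage,
    png,
    tiff
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
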