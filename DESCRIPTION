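Package: mlgscan
Title: Unsupervised Anomaly Scans of Multilocus Genotype Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Genome scans for anomalous patterns of genetic variation from
    unphased diploid genotypes at biallelic SNPs. Summarises multilocus
    genotype (MLG) diversity in sliding SNP windows with eight per-window
    statistics, extracts moment-based and B-spline functional-data-analysis
    features over stretches of consecutive windows, scores each stretch with
    Mahalanobis-distance, isolation-forest and one-class support-vector-machine
    anomaly detectors, calibrates scores into inflation-corrected p-values
    under an F-distribution null, and characterises significant regions by
    intersecting them with genomic annotation and running permutation-calibrated
    enrichment tests. Includes a synthetic genotype simulator with injectable
    anomalous regions so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    splines,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
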