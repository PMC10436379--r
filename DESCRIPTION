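Package: pmdscape
Title: Partially Methylated Domain Calling and Rare-Cell Hypomethylation Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of partially methylated domains (PMDs) and nested
    preserved methylation islands (PMIs) from sparse single-cell bisulfite
    CpG calls by 100-kb sliding-window bimodal valley thresholding, with
    core-domain designation by quantile normalization across sample sources;
    a bin-level copy-number aberration score; 10-kb methylation-array metrics;
    interval-Jaccard and correlation/jackknife heterogeneity indices; a
    domain-gene differential-expression screen with hypergeometric gene-set
    enrichment; and a per-read hypomethylation detector for long-read
    methylation calls from circulating-tumor-cell-enriched blood, including
    lambda spike-in QC and an in-silico spike-in precision-recall model.
    Ships synthetic-methylome generators so the whole pipeline is testable
    end-to-end without external data.
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
    IRanges,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
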