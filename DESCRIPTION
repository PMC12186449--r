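Package: lowmeth
Title: Low-Pass Whole-Genome Bisulfite Methylation and Copy-Number Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for low-pass whole-genome bisulfite sequencing (WGBS)
    cohorts: reads Bismark-style cytosine reports and coverage files, computes
    CpG beta values with strand collapsing, imputes missing betas per sample
    with gradient-boosted regression trees on neighbour and cross-sample
    features, calls reference-free copy number from binned fragment coverage
    via circular binary segmentation with absolute copy-state thresholds,
    matches loci against methylation-array probe manifests, selects the most
    variably methylated CpGs and collapses them to unique genomic regions,
    and simulates complete cohorts (bimodal methylomes, binomial read
    sampling, CNV-scaled fragment coverage, array-like counterparts) with
    known truth for validation.
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
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
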