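Package: somevo
Title: Somatic Evolution Analysis of Tumor Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-scale somatic-evolution analyses for tumor whole-genome
    sequencing: cancer cell fraction (CCF) and binomial-interval clonality
    calls from read counts, VAF-based purity QC and NRPCC power filtering,
    genomic-instability metrics (whole-genome duplication, PGA, PGAn) and
    kataegis detection by piecewise constant fitting, recurrent copy-number
    calling by permutation against a random background, 100-kb-bin non-coding
    hotspot scanning, the wCCF intra-tumor-heterogeneity statistic, and
    population-level chronological ordering of genomic events with a
    Plackett-Luce model over sampled per-tumor rankings. A synthetic
    tumor-cohort simulator with full truth tables drives testing end to end.
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
    tools,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
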