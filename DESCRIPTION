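Package: slafbsa
Title: Bulked Segregant Analysis of SLAF-Seq Tag Data with RIL Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Localize major quantitative trait loci from pooled
    reduced-representation sequencing of biparental populations.
    Provides a recombinant-inbred-line (RIL) simulator with Haldane
    crossover placement and explicit selfing, extreme-bulk selection,
    per-tag read-depth simulation, SLAF tag quality filtering and
    clustering, parent-polarized marker calling, SNP-index and
    delta(SNP-index) association scanning with an empirical nearest-rank
    percentile threshold and consecutive-marker hot-region detection,
    single-marker ANOVA with phenotypic-variance-explained estimates,
    2^-ddCt relative expression, and in-silico CAPS/InDel diagnostic
    marker design (restriction-site search, digest-fragment prediction,
    amplicon sizing).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
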