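Package: corrmr
Title: Two-Sample Mendelian Randomization with Correlated Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidy pipeline for two-sample Mendelian randomization from
    GWAS summary statistics: reading and allele-harmonizing exposure and
    outcome association tables, constructing a multi-allelic genetic
    instrument (genome-wide significance, replication and availability
    filters, greedy LD pruning), quantifying instrument strength (variance
    explained and F-statistics across LD thresholds), estimating the causal
    effect with a profile maximum-likelihood model that accounts for
    linkage-disequilibrium correlation between variants (with a
    correlated-variant IVW cross-check), and rescaling log-odds effects to
    a trial-equivalent exposure increment. Includes a summary-level and
    individual-level simulator of two-sample GWAS summary statistics with
    known causal effect, LD and optional horizontal pleiotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
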