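Package: fmtengraft
Title: Donor Microbiota Engraftment Analysis for Sham-Controlled FMT Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies donor microbiota engraftment after fecal microbiota
    transplantation (FMT) from longitudinal 16S feature tables. Implements the
    abundance-based Sorensen similarity (1 - Bray-Curtis) engraftment
    classifier used as a randomized trial's primary endpoint, donor-similarity
    trajectories, tracking of newly appearing OTUs, and a multinomial-mixture
    source attribution estimated by EM (a deterministic counterpart to Bayesian
    source tracking). Also provides rarefaction, alpha/beta diversity, PCoA and
    ANOSIM wrappers, a simplified LEfSe-like differential-abundance screen,
    trial endpoint statistics (flare rules, remission rates with
    dropout-as-flare imputation, Fisher/Wilcoxon tests, Kaplan-Meier and
    log-rank, two-proportion sample size), and a synthetic longitudinal cohort
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    picante,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
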