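Package: drcphenotype
Title: Phenotypic DNA Repair Capacity Profiling from gamma-H2AX Repair
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a production-decay kinetic model to gamma-H2AX fluorescence
    time courses measured in peripheral blood mononuclear cell (PBMC)
    subtypes after a 3-Gy radiation challenge, deriving per-donor DNA repair
    capacity parameters (production rate Kprod, repair rate Kdec, residual
    damage Fres). Provides a seeded synthetic generator for matched
    case-control cohorts, a shadow-feature (Boruta-style) relevance filter
    over the kinetic parameters, random-forest case-control classification
    with out-of-bag evaluation, and the accompanying inference toolkit:
    ROC/AUC, percentile bootstrap confidence intervals, DeLong's test for
    paired AUCs, Fisher's exact accuracy comparison, Spearman correlation and
    the Mann-Whitney U test. An end-to-end pipeline orchestrates simulate,
    fit, select, classify and report stages with full seed provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
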