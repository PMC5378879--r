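Package: ncasurv
Title: Network-Guided Discovery of Prognostic Gene Modules from Survival Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows connected gene modules on a protein-protein interaction
    network by population hill-climbing, scoring each candidate module by the
    significance of a multivariate Cox proportional-hazards model (the
    negative log10 p-value of the global score test, NLLRT). Supports
    single-cohort objectives and multi-cohort composite objectives (reference
    cohort NLLRT minus the range over the remaining cohorts) for deriving
    biomarkers that transfer across datasets. Includes consensus-signature
    extraction from the final module population, risk-group evaluation
    (prognostic index, median split, log-rank test, Harrell's concordance
    index), empirical significance against random same-size gene signatures,
    cohort preprocessing (log2, quantile normalization, cross-cohort gene
    harmonization), and a synthetic-data generator planting a prognostic
    connected module in a scale-free network.
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
    igraph,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
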