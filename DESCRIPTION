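Package: frogclock
Title: Epigenetic Clocks and Age-Related Methylation Analysis for Clawed Frogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and cross-validates elastic-net DNA methylation clocks for
    Xenopus laevis, Xenopus tropicalis, and dual human-frog cohorts, using
    species-aware age transformations (log-linear normalization at sexual
    maturity, relative age as the fraction of maximum lifespan). Includes
    epigenome-wide association screening of age with Stouffer meta-analysis
    across species, hypergeometric enrichment of age-related CpGs against
    annotation sets such as Polycomb (PRC2) targets on a restricted background,
    correlation-distance hierarchical clustering for cohort QC, and a synthetic
    cohort generator that emulates the statistical structure of cross-species
    methylation array studies so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
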