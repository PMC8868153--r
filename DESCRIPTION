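Package: orgpigsim
Title: Stochastic Simulation of Organic Pig-Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of breeding programs for organic pig
    production. Implements a ten-trait genetic architecture with genetic,
    environmental and phenotypic covariance matrices, economic breeding goals
    and aggregate-genotype correlations, pedigree inbreeding and sparse
    inverse numerator-relationship matrices, multivariate pedigree BLUP with
    general missing-trait patterns, and truncation selection over half-year
    time steps with overlapping generations in two scheme designs (organic
    sires versus conventional sires). Downstream analysis turns replicate
    trajectories into annual genetic gain (total and per trait, in EUR and
    genetic-standard-deviation units) and rate of inbreeding per generation.
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
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
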