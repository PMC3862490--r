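Package: cartrend
Title: Spatially Explicit Population Trends from Route-Count Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical Bayesian estimation of population trends from
    route-level count surveys (North American Breeding Bird Survey style)
    on a longitude/latitude degree-block lattice. Observed route counts are
    modeled as Poisson with a log-linear mean combining year intercepts,
    observer(-route) random effects, and per-year intrinsic conditional
    autoregressive (ICAR) spatial effects. A Metropolis-within-Gibbs
    sampler (compiled core) returns posterior draws, from which
    interval-specific geometric-mean trends are derived per cell and
    aggregated to arbitrary reporting regions by area-weighted
    post-stratification on the sphere. Includes a synthetic-data
    generator with known truth, Gelman-Rubin diagnostics, and utilities
    for comparing the precision of spatial and non-spatial trend
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
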