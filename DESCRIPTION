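Package: radonmap
Title: Lognormal Kriging of Indoor Radon and Bayesian Spatial Disease Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological (region-level) studies of indoor radon and
    cancer incidence. Implements ordinary lognormal kriging of point radon
    measurements with an unbiased back-transform, aggregation of the
    interpolated field to administrative regions, indirect standardization of
    cancer counts by sex and five-year age group (standardized incidence
    ratios), and a Bayesian hierarchical Poisson model with a Besag intrinsic
    conditional autoregressive spatial effect plus unstructured heterogeneity
    (the BYM convolution), fitted by adaptive Metropolis-within-Gibbs MCMC
    with Gelman-Rubin convergence diagnostics. A synthetic-data generator
    reproduces the statistical structure of a national radon survey and a
    cancer registry so the full pipeline is testable without restricted
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
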