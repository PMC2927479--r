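Package: birthmix
Title: Finite Normal Mixture Modeling of Birthweight Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models birthweight distributions as finite normal mixtures with a
    data-determined number of components. Provides maximum-likelihood fitting by
    EM with direct numerical refinement, order selection by AIC, BIC and a
    flexible information criterion whose penalty adapts to sample size and data
    configuration, meta-sample confidence intervals with simulation-based bias
    adjustment and an overlap-corrected critical multiplier, the contaminated
    normal and 2-component mixture competitor models, truncated-mixture
    simulation designs, and drivers for order-selection and interval-coverage
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
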