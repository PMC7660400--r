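Package: flexlinks
Title: Flexible-Links Models for the Number of Trophic Links in Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian models for the number of trophic links L in a food web
    of S species. Implements the flexible-links shifted beta-binomial model,
    which constrains L to the ecologically permitted interval [S-1, S^2],
    alongside three classical competitors (link-species scaling, constant
    connectance, power law) with negative binomial observation models.
    Provides seeded MCMC fitting with convergence diagnostics, MAP and
    maximum-likelihood estimation, Pareto-smoothed importance-sampling
    leave-one-out cross-validation (PSIS-LOO) for model comparison, derived
    probability distributions for connectance and linkage density, analytic
    Z-scores for link counts, network-area relationship predictions, and
    stability limits under May's criterion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
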