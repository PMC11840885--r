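Package: dietsub
Title: Causal Effects of Capped Dietary Substitution Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification and efficient estimation of average causal
    effects under capped dietary substitution strategies: interventions
    that replace one discrete food exposure with a substitute food up to
    a cap, depending on the natural (pre-intervention) intake. Provides
    outcome-regression, inverse-probability-weighted, and targeted
    maximum likelihood estimators of the counterfactual mean and of
    marginal structural working-model projections, with influence
    function based inference, positivity diagnostics, conditional
    density estimation for discrete exposures, optional cross-fitting,
    and a Monte Carlo simulation harness with deterministic numerical
    oracles for the true estimands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    mgcv,
    splines,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
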