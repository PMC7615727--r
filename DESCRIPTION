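Package: auximp
Title: Auxiliary Variable Selection Strategies for Multiple Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulation framework for evaluating data-driven strategies for
    selecting auxiliary variables for the imputation model in multiple
    imputation (MI) of a single incomplete continuous outcome. Provides
    power-calibrated multivariate-normal scenario design, missing-at-random
    missingness generation with quadrature-calibrated intercepts, a proper
    Bayesian linear-regression imputation engine with Rubin's rules pooling
    and Barnard-Rubin degrees of freedom, eight auxiliary-variable selection
    strategies (correlation screening, tests of the MCAR assumption,
    principal-component auxiliaries, forward and forward-stepwise selection,
    forward selection on the fraction of missing information, and the LASSO)
    alongside complete-case and full-model benchmarks, and the standard
    simulation performance measures with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Matrix,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
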