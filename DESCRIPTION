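Package: semmed
Title: Causal Mediation Analysis with Exposure-Induced Confounding via Linear
    Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of total, natural direct, natural indirect, and
    controlled direct effects of a binary exposure on a continuous outcome
    through a continuous mediator when an exposure-induced (intermediate)
    confounder of the mediator-outcome relationship is present.  A recursive
    three-equation linear structural equation model is fitted by equation-wise
    least squares; estimands are obtained both in closed form (estimation by
    combination, with delta-method standard errors) and by Monte Carlo
    g-computation (with bootstrap standard errors).  Includes diagnostics for
    choosing between the Robins-Greenland (no exposure-mediator interaction)
    and Petersen (controlled direct effect constant in the natural mediator
    value) parametric identification assumptions, a sensitivity analysis for
    unmeasured mediator-outcome confounding based on the residual correlation
    of a reduced outcome model, a synthetic-data generator for the full system
    including an unmeasured confounder of the intermediate-outcome edge, and
    an exact quadrature truth oracle for the estimands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
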