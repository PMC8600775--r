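Package: qlqmap
Title: Mapping the EORTC QLQ-C30 to EQ-5D-3L Utilities with Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates EQ-5D-3L health utilities (UK tariff) from EORTC
    QLQ-C30 quality-of-life scores for cost-effectiveness analysis.
    Implements the adjusted limited dependent variable mixture model
    (ALDVMM): a finite mixture of normals censored to the bounded utility
    scale, with a probability mass at full health, an infeasible gap just
    below it, and covariate-dependent component membership. Also provides
    indirect response mapping via per-dimension ordered probits, a
    random-effects linear comparator, model-comparison metrics and
    diagnostics, a predictive simulation audit, and a calibrated synthetic
    panel-data generator for testing mapping pipelines without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
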