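Package: groupdro
Title: Worst-Case Predictive Performance over Patient Subpopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and evaluation of clinical risk prediction models with an
    emphasis on worst-case performance across pre-defined patient subpopulations.
    Implements group distributionally robust optimization (GroupDRO) with
    exponentiated-gradient weight updates, additive loss adjustments (size-based
    and marginal-entropy-baselined), a metric-steered DRO variant instantiated
    with the AUC, subpopulation-balanced minibatch sampling, worst-case early
    stopping and model selection, and a disaggregated evaluation engine (AUC,
    cross-entropy loss, absolute calibration error) with stratified percentile
    bootstrap confidence intervals and paired differences against a reference
    model. A synthetic subpopulation-cohort generator with controllable group
    sizes, outcome incidences and group-dependent feature-outcome relationships
    supports end-to-end experimentation without access to restricted electronic
    health records data.
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
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
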