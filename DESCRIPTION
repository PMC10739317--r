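Package: hillmix
Title: Hill-Based Dose-Response and Mixture Additivity Modelling for
    Reporter-Gene Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models concentration-response data from receptor
    transactivation (reporter-gene) bioassays and predicts the joint
    activity of chemical mixtures. Implements the multi-ligand
    generalisation of the Hill equation derived from mass-action receptor
    occupancy ("generic response addition", GRA), classical concentration
    addition (CA), Levenberg-Marquardt curve fitting with
    heteroscedasticity-robust uncertainty, Monte-Carlo 95% prediction
    envelopes, and an additivity / synergy / antagonism verdict for
    observed mixture curves. Ships a synthetic plate generator emulating
    estrogen-receptor CALUX experiments (serial dilutions, an estradiol
    reference curve, QC wells, multiplicative noise) so the full pipeline
    is testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
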