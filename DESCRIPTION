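Package: ddgbounds
Title: Per-Mutation Error Bounds for FoldX Stability-Change Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the uncertainty of FoldX-predicted protein folding and
    binding stability changes (ddG, kcal/mol). Models the absolute prediction
    error of each mutation as a linear function of FoldX energy terms, their
    standard deviations over molecular-dynamics snapshots, and biochemical
    properties of the mutated residue; selects predictors by best-subset or
    stepwise search under BIC; converts out-of-sample 95 percent prediction
    intervals into per-mutation error bounds; validates bound coverage by
    leave-one-system-out cross-validation; and classifies mutations as
    stabilizing, neutral or destabilizing with and without the bounds. Includes
    readers for FoldX "Dif" tables and DSSP output, and a synthetic-data
    generator with known ground truth for calibration and recovery testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
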