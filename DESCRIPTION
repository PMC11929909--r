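Package: qpopr
Title: Quadratic Phenotypic Optimization for Ex Vivo Drug Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quadratic phenotypic optimization platform
    (QPOP) style ex vivo combinatorial drug-sensitivity screens. Constructs the
    155-run orthogonal array composite design for a 12-drug, three-dose panel,
    normalizes CellTiter-Glo-style plate readouts to cell viability with
    Z'-factor and SSMD quality gating, fits the second-order response-surface
    regression and ranks all one-, two- and three-drug dose combinations,
    validates pairs by Chou-Talalay combination index and Bliss independence
    scoring, and computes clinical concordance statistics (ROC/AUC, cutoff
    selection, odds ratio with Fisher's exact test, cohort-level combination
    frequencies). Includes a synthetic-data generator that simulates
    luminescence plates from known quadratic viability surfaces so every stage
    has parameter-recovery tests without external data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
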