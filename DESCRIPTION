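Package: combindex
Title: Dose-Response Modelling and Drug Combination Index Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-drug dose-response experiments and two-drug
    checkerboard combination experiments from plate-reader data. Fits five
    dose-response models (the Chou-Talalay median-effect equation and the
    two-, three- and four-parameter log-logistic curves), screens replicate
    outliers with an iterative Grubbs test, computes absolute IC50 values,
    and scores drug interaction over a dose matrix with five combination
    index models (response additivity, highest single agent, Bliss
    independence, Loewe additivity and zero interaction potency). Includes
    a seeded synthetic plate generator with known ground truth, tidy
    tabular results, ggplot2 figures and CSV/PNG/PDF report export.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
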