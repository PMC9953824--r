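Package: combrisk
Title: Combining Mendelian and Relative-Hazard Breast Cancer Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining a two-gene Mendelian (family-history based)
    breast cancer risk model with a Gail-style relative-hazard risk-factor
    model. Implements exact carrier-probability computation by pedigree
    peeling, crude (competing-mortality adjusted) future-risk projection,
    penetrance modification of the non-carrier hazard by covariate relative
    hazards, stacked logistic and Fine-Gray ensembles over base-model
    predictions, least-squares importance fitting for covariate shift,
    a pedigree/cohort simulator, and a censoring-aware (IPCW) evaluation
    suite with bootstrap model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
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
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
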