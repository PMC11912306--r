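Package: zfetr
Title: Analysis of Zebrafish Embryo Acute Toxicity Test Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the zebrafish embryo acute toxicity test (ZFET):
    a controlled 52-term vocabulary of morphological effects with
    developmental time windows, a per-embryo observation data model with
    CSV import/export and validation, binomial control-quality gating,
    two-parameter log-logistic and Weibull dose-response modelling with
    AIC-based model selection and validity rules, effective-concentration
    and sensitivity-ratio estimation, phenotypic effect fingerprints with
    Ward hierarchical clustering and PCA-based effect ranking,
    effect-propagation correlation between developmental time points,
    and a seeded synthetic-study generator with known ground truth for
    end-to-end validation of the pipeline.
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
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
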