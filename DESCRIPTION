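Package: itaemt
Title: Infiltrating T-Cell Abundance and EMT Expression as a Combined
    Prognostic Factor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based scoring of infiltrating T-cell abundance (ITA) and
    epithelial-mesenchymal transition (EMT) gene expression from bulk
    transcriptomes, single-sample gene-set enrichment (ssGSEA),
    expression-based tumor purity (ESTIMATE-style stromal/immune scores with
    the cosine purity transform), purity residualization of biomarker scores,
    and survival analysis: continuous-score Cox proportional-hazards models
    with IQR-scaled hazard ratios, median dichotomization and 2x2 EMT-by-ITA
    grouping with Kaplan-Meier/log-rank comparison, per-gene Cox screening
    controlling for ITA, and second-cohort validation. Ships a synthetic
    cohort generator with compartment-mixture expression and
    proportional-hazards survival with known coefficients so the full
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
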