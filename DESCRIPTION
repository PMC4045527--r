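Package: fetaldose
Title: Foetal Absorbed Dose and Radiation Risk from Diagnostic Radiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates foetal absorbed dose from diagnostic radiology
    exposures (radiographs, fluoroscopic screening, dose-area-product
    records and computed tomography) by combining reconstructed entrance
    surface dose or DAP with depth-indexed normalized uterus dose
    coefficients and gestational-age-dependent foetal size factors, then
    converts dose to stochastic risk under the linear no-threshold model
    for four endpoints (childhood cancer, hereditary effects, IQ decline,
    severe mental retardation).  Includes the clinical "1 in N" risk
    rendering convention, per-cohort dose histograms and risk-band
    tables, and deterministic generators for synthetic coefficient
    tables and synthetic exposure cohorts so the full pipeline is
    testable without licensed coefficient publications.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
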