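Package: gmmquant
Title: Targeted Quantification of Uremic Toxins and Bile Acids from
    MRM Peak-Area Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for targeted LC-MS/MS quantification of
    gut microbiota-derived metabolites (uremic toxins and bile acids) in
    plasma and feces. Starting from vendor-style integrated MRM peak-area
    tables, the package fits matrix-matched calibration curves on
    internal-standard response ratios, estimates limits of detection and
    quantification, back-calculates sample concentrations across serial
    dilutions, computes method-validation metrics (precision, recovery,
    matrix effect), applies a detection-rate/imputation/internal-standard
    quality-control cascade, and runs covariate-adjusted cohort statistics
    with multiple-testing correction. A synthetic-data module emulates a
    dialysis-patient versus healthy-control cohort and a triple-quadrupole
    instrument response, so the full pipeline is testable without any
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
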