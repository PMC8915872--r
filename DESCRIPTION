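Package: ttcair
Title: Derivation of Inhalation Threshold of Toxicological Concern Values
Version: 0.1.0
Authors@R:
    person("ttcair", "maintainers", email = "maintainers@ttcair.invalid",
           role = c("aut", "cre"))
Description: A tested pipeline for deriving inhalation Threshold of
    Toxicological Concern (TTC) values from heterogeneous repeat-dose
    inhalation study records: study-length annotation, unit standardization
    between ppm and mg/m3 tracks, ambiguous-record and species filtering,
    Tukey-fence outlier screening with per-substance minimum representative
    values, empirical (and bootstrapped) 5th percentiles with normality and
    Kolmogorov-Smirnov diagnostics, air-concentration and body-dose TTC
    formulas, the tiered Kroes decision-tree assignment, aquatic
    mode-of-action consensus classification, and cross-dataset verification
    statistics. Includes a synthetic study-record generator with known
    ground truth so every stage runs and is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
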