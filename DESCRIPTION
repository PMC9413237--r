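Package: popvitro
Title: Population-Based In Vitro Toxicodynamic Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for population-based in vitro cytotoxicity
    screens run across panels of genotyped human cell lines. Simulates
    384-well concentration-response screens with vehicle and positive
    controls, normalizes and quality-controls plate luminescence, fits
    hierarchical Bayesian random-effects downward Hill models with
    Student-t errors by MCMC, derives per-individual EC10 points of
    departure, quantifies the toxicodynamic variability factor (TDVF05)
    with full posterior uncertainty, and maps the point-of-departure
    phenotype genome-wide with covariate-adjusted linear models, genomic
    control diagnostics, a GRM-based mixed-model alternative, and
    ancestry-stratified z-score meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
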