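Package: pglmetabo
Title: Metabolomic Genotyping of Paragangliomas from 1D HRMAS NMR Spectra
Version: 0.1.0
Authors@R:
    person("pgl", "metabo developers", email = "pglmetabo@example.org",
           role = c("aut", "cre"))
Description: Quantifies succinate, glutamate, glutathione, energy
    phosphorylated compounds (ATP/ADP/AMP) and catecholamines from processed
    1D proton HRMAS NMR spectra of intact tumor tissue by spectral region
    integration with external-standard (PULCON-style) calibration, and
    discriminates SDHx-, VHL-related and apparently sporadic paraganglioma
    metabotypes with a from-scratch two-component NIPALS PLS-DA under
    stratified Monte-Carlo cross-validation. Includes exact and asymptotic
    Mann-Whitney U tests and Spearman rank correlations for the univariate
    layer, a synthetic spectrum and cohort generator for fully reproducible
    testing, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
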