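Package: agiflow
Title: Database-Guided Automated Gating and Identification for Blood
    B-Cell and Plasma-Cell Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for standardized in-depth dissection of circulating
    B-lymphocyte and plasma-cell populations from multiparameter flow
    cytometry data.  Provides minimal FCS 3.x and CSV event input/output
    with spillover compensation and display transforms, datafile quality
    control (cell yield, flow-rate stability, compensation residuals and
    staining ranges), a Boolean-gating population taxonomy of 117
    B-lymphocyte and plasma-cell subsets, construction of a labelled
    reference database with leave-one-file-out consistency checks,
    automated database-guided gating and identification (AGI) by
    density-peak clustering plus canonical-analysis classification in
    two-step and hierarchical variants with a maturation-trajectory
    classifier, a synthetic whole-blood sample generator with planted
    ground truth, and method-comparison statistics (per-population
    correlation, coefficients of variation, Bland-Altman bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
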