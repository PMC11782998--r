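Package: mrmlfq
Title: Targeted MRM Quantitation and Label-Free Differential Expression
    for Knockout Proteome Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A computational pipeline for phenotyping knockout-mouse
    proteomes by mass spectrometry. Provides an exact monoisotopic
    mass and m/z engine for light and stable-isotope-labelled peptides
    and their y/b fragment ions (transition-table construction for
    multiple reaction monitoring assays), ratio-to-heavy quantitation
    against stable-isotope-labelled internal standards with weighted
    calibration, precision/accuracy validation and rdotp identity
    scoring, and a label-free differential-expression workflow
    (top-N protein roll-up, condition-mean and near-zero-variance
    filtering, midpoint zero imputation, trimmed-mean-of-M-values
    normalisation, ANOVA-component batch removal, voom precision
    weights, empirical-Bayes moderated t-tests, fold-change/FDR
    calling, hypergeometric over-representation and cross-tissue
    overlap analysis). Synthetic-data generators emulate co-eluting
    MRM chromatograms, serial-dilution calibration ladders, and
    multi-tissue protein abundance matrices with genotype, batch,
    and covariate structure, so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    fgsea,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    caret,
    withr,
    optparse
Config/testthat/edition: 3
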