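Package: glycospot
Title: Antibody-Spot MALDI Glycan Quantification and Fibrosis Panel Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for antibody-capture spot-array MALDI imaging
    of IgG N-glycans. Parses Oxford-nomenclature glycan names into
    monosaccharide compositions and theoretical adduct m/z values, converts
    per-pixel spot spectra into per-channel relative-percentile glycan
    profiles (TIC normalization, windowed peak-area extraction, pixel
    averaging), screens features across three fibrosis groups by one-way
    ANOVA with Tukey post-hoc timing classification, selects a minimal
    biomarker panel by iterative elimination driven by Hoeffding's D
    similarity and random-forest importance, and evaluates pairwise group
    discrimination with four cross-validation schemes, DeLong AUC confidence
    intervals and fixed-specificity operating points. A seeded
    logistic-normal cohort simulator with planted group effects and
    correlated decoy features makes every stage testable without patient
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
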