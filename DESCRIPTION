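Package: ecsubtype
Title: Whole-Exome Molecular Subtyping of Endometrial Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical determination of the four TCGA endometrial
    cancer molecular subtypes (POLE, MSI, CN-low, CN-high) from
    whole-exome sequencing derived inputs: somatic small-variant calls,
    copy-number segment profiles, and microsatellite-instability status.
    Implements the ultramutated POLE rule on the pyrimidine-collapsed
    substitution spectrum, the MSI-high gate, and a Gaussian naive Bayes
    model of copy-number cluster-4 membership built on segment-derived
    features, with stratified cross-validation, confusion-matrix and
    chi-square concordance statistics, Kaplan-Meier / log-rank survival
    comparison, and a synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC
Config/testthat/edition: 3
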