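Package: maldisubtype
Title: Molecular Subtyping of Tumors from MALDI Imaging Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying tumor molecular subtypes
    from MALDI imaging mass spectrometry (MALDI-IMS) of tissue microarrays.
    Provides spectral preprocessing (convolution baseline removal, total-ion-count
    normalization, peak picking to an aligned m/z axis), cross-dataset feature
    parity matching, stratified balanced dataset construction, Gini-importance
    proteomic signature selection, consensus-based exclusion of stroma-derived
    spectra, triplicate random-forest subtype classification with one-vs-one
    multiclass AUC evaluation, peptide annotation against an LC-MS/MS reference
    list, and NanoString-style count normalization for ground-truth subtype
    labeling.  A synthetic spatial mass-spectrometry data generator with planted
    subtype and compartment markers makes every stage testable without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
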