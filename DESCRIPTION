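Package: octreport
Title: Structured Measurement Extraction from Ophthalmic OCT Report Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts raster report images produced by optical coherence
    tomography (OCT) devices into standardized, structured, longitudinal
    measurement records. A layout catalog maps each report type to named
    pixel regions; a header-based classifier identifies the report type;
    an area router sends numeric regions to a trainable scene-text
    recognizer (convolutional feature extractor, bidirectional LSTM
    sequence model, attention decoder) and tomographic regions to a
    pluggable finding classifier; rule-based disease-activity labels and
    CSV / OMOP-CDM-shaped measurement rows are produced. A built-in
    synthetic report renderer with ground-truth sidecars provides training
    corpora and test oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    glmnet,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
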