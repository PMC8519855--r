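Package: spicetest
Title: Simple Permutation-Based Intermodal Correspondence Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests whether two imaging modalities correspond more strongly
    within subjects than between subjects (the SPICE test). Subject-level
    vertex-wise brain maps from two modalities are compared by the mean
    within-subject spatial correlation, and a null distribution is built by
    permuting one modality's maps across subjects, avoiding spatial null
    models and their covariance-stationarity assumptions. Includes a
    bi-modal simulation framework for type-I-error and power studies,
    readers and writers for GIFTI surface data, FreeSurfer per-vertex
    morphometry and annotation files, region-stratified testing against a
    parcellation with Bonferroni correction, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
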