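Package: lipidmsi
Title: Spatiotemporal MALDI Mass Spectrometry Imaging Lipidomics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for MALDI mass spectrometry
    imaging (MSI) studies of the developing brain lipidome: simulation of
    study-structured imaging datasets with ground truth, global maximum-pixel
    intensity normalization, region-of-interest aggregation, winsorized
    z-score preprocessing, per-feature linear models with decile-stratified
    selection of supplement-elevated peaks, accurate-mass lipid annotation
    with knowledge-based filtering, class and pathway over-representation
    analysis with Holm correction, and PCA biplot / hierarchical clustering
    exploration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
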