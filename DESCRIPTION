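Package: somatlas
Title: Molecular Formula Assignment and Compositional Network Analysis for
    Ultrahigh-Resolution Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-targeted analysis of complex soluble organic mixtures from
    ultrahigh-resolution mass spectrometry peak lists. Reads and recalibrates
    peak lists, assigns elemental compositions to accurate masses by bounded
    combinatorial enumeration with senior-rule and elemental-ratio validation,
    computes compositional descriptors (H/C, O/C, double-bond equivalents,
    aromaticity equivalents, chemical families, homologous series), builds
    mass-difference networks over assigned formulas, and classifies multi-sample
    studies with NIPALS principal component analysis including work/prediction
    set projection and cross-validated Q2. Ships a synthetic-data generator
    with planted ground truth so every stage of the pipeline can be validated
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
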