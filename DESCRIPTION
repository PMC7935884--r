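Package: traumaScreen
Title: Quantification Pipeline for a C. elegans Blunt-Force Trauma
    Neurodegeneration Screen
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scoring machinery for a large-particle flow-cytometry (COPAS)
    RNAi screen of trauma-induced dopaminergic neurodegeneration in
    Caenorhabditis elegans, together with the surrounding transcriptomic and
    behavioral quantifications. Provides gating of per-object cytometry event
    tables, the normalized Dopaminergic GFP Index with quadrature error
    propagation and confidence-interval hit calling, z-score cross-correlation
    of stress-response fold-change signatures, fold-change/FDR differential
    expression filtering and set overlaps, chemotaxis/paralysis/nose-touch
    assay metrics, delta-Ct qPCR quantification with geometric-mean
    housekeeping normalization, and a fully seeded synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: FlowCytometry, GeneExpression, DifferentialExpression,
    Transcriptomics, QualityControl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
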