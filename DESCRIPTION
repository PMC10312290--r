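Package: ccflow
Title: Cortico-Cerebellar Task Connectivity and Activity-Flow Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for block-design dual-task fMRI studies of the
    cortico-cerebellar system on parcellated BOLD time series. Implements
    block-design general linear model activation mapping with a canonical
    double-gamma haemodynamic response, a principal-component task decoder,
    time-varying functional connectivity by multiplication of temporal
    derivatives, signed-modularity community detection with consensus
    clustering and resolution-stability analysis, participation-coefficient
    topology contrasts, and structure-informed activity-flow mapping through
    directed cortico-ponto-cerebellar and cerebello-thalamo-cortical
    connectomes, with permutation-based edge and prediction statistics.
    Includes motion quality control (framewise displacement, DVARS) and a
    synthetic-cohort generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
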