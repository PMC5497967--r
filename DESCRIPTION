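Package: afcommnet
Title: Communication Network Analysis of Atrial Fibrillation Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional connectivity analysis of multi-electrode intracardiac
    electrograms recorded during atrial fibrillation. Provides ventricular
    far-field removal by mean QRS-T template subtraction, windowed pairwise
    mutual information estimation with the Kraskov-Stoegbauer-Grassberger
    k-nearest-neighbor estimator, construction of density-thresholded binary
    communication networks, small-world network metrics normalized against
    matched Erdos-Renyi null ensembles, and paired nonparametric comparison
    of density-resolved network parameter curves between conditions. A
    synthetic-data module simulates coupled quasi-periodic atrial activation
    with a planted ground-truth coupling network and ventricular far-field
    contamination, so the entire pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    signal,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
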