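Package: octsum
Title: Summarisation of SDOCT Volumes by Relevant B-Scan Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates visual summaries of spectral-domain optical coherence
    tomography (SDOCT) volumes. B-scans showing structural abnormality are
    detected with a compact convolutional neural network trained de novo
    under a class-balanced cross-entropy loss, after retina localisation by
    Gaussian-derivative filtering, Otsu thresholding and connected-component
    analysis. Flagged B-scans are grouped into regions and reduced to
    first/median/last keyframes to form the summary. Includes a synthetic
    AMD phantom generator (layered retina, drusen, pigment epithelial
    detachment, geographic atrophy, epiretinal membrane, acquisition
    artifacts) so the full pipeline can be exercised without clinical data,
    plus evaluation utilities (ROC AUC, confusion metrics, rank-sum tests,
    cross-validation reports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
biocViews: Software, Classification, Visualization
RoxygenNote: 7.3.3
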