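Package: edges
Title: Spatially Constrained Coupled Non-Negative Matrix Factorization
    for Spatial Transcriptomics Enhancement
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint enhancement of imaging-based spatial transcriptomics (ST)
    with a reference scRNA-seq atlas through a coupled non-negative matrix
    factorization. Shared genes bridge the two modalities through a common
    gene-factor matrix and the scRNA-seq cells bridge shared and unmeasured
    genes through a common cell-factor matrix, while a mutual k-nearest-
    neighbor graph Laplacian over the spatial coordinates keeps neighboring
    cells' latent loadings similar and a squared-L1 column penalty keeps cell
    loadings sparse. The fitted model predicts the spatial expression of
    genes absent from the ST panel, denoises the measured panel, and scores
    gene abundance. Includes the matching cross-validation protocol and
    evaluation metrics (Pearson correlation, structural similarity,
    min-max-scaled RMSE, Jensen-Shannon divergence, rank-aggregated accuracy
    score, Moran's I, Hedges' g), a planted-factor synthetic data generator,
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
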