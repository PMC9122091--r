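Package: vertexlmm
Title: Mixed-Model and GLM Mass-Univariate Vertexwise Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-univariate association mapping for high-dimensional,
    spatially correlated gray-matter surface measurements (cortical and
    subcortical thickness and surface area). Implements per-vertex general
    linear models with the usual covariate sets (demographics, global and
    modality-specific principal components) and MOA-style linear mixed models
    that fit all vertices jointly as random effects through brain-relatedness
    matrices, estimated by average-information REML. Includes morphometricity
    estimation, a synthetic-cohort generator with mesh-local and
    confounder-driven long-range correlation, phenotype simulation under null
    and alternative hypotheses, cluster-level error metrics (inflation factor,
    FPR, TPR, vertex and cluster FWER, cluster FDR, mapping precision,
    FWER-calibrated power), and out-of-sample linear prediction from
    significant vertices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
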