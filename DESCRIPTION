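Package: netEntropy
Title: Transcriptomic Heterogeneity as Log-Determinant Entropy of Gene
    Regulatory Network Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models and quantifies transcriptomic heterogeneity as the
    log-determinant entropy of a multivariate Gaussian gene-expression
    model, and implements four statistically defined mechanisms by which
    that entropy can increase in cancer: regulatory switches (finite
    Gaussian mixtures), increased variation in an expression regulator
    (a steady-state structural model coupling DNA copy number to
    expression through the gene-gene interaction network), temporary
    disturbances (a first-order vector autoregressive process with a
    one-time shock), and weakened conditional dependencies (block-scaled
    partial-correlation matrices and in silico gene knockouts). Includes
    Ledoit-Wolf/Schafer-Strimmer shrinkage covariance estimation with an
    equal-size subsampling protocol for two-group entropy comparison,
    sparse structural-model fitting by equation-wise L1-penalized
    regression with an unpenalized cis-effect, regularization-path edge
    counting, and a synthetic two-group cohort generator for end-to-end
    evaluation.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    MASS,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GraphAndNetwork, NetworkInference, GeneExpression, CopyNumberVariation, Transcriptomics
RoxygenNote: 7.3.3
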