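Package: remlvc
Title: Restricted Maximum-Likelihood Estimation of Latent Variance
    Components in Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic restricted maximum-likelihood (REML) inference for a
    random-effects model of gene expression with known and latent variance
    components. Given a samples-by-genes expression matrix and known sample
    covariates (e.g. batch indicators or genotype principal components), the
    package infers latent factors orthogonal to the known covariates by
    probabilistic PCA on the orthogonal-complement subspace, and estimates all
    random-effect covariance parameters and the residual variance in closed
    form, without numeric likelihood optimization. Includes covariate
    screening by single-covariate variance explained, a generative-model
    simulator, a numeric quasi-Newton likelihood maximizer used as a test
    oracle, and broom-style tidiers and ggplot2 autoplot methods for fitted
    objects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
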