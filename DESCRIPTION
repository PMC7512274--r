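Package: megvar
Title: Latent-Variable Graphical Models for Vector Autoregressions by
    Maximum-Entropy Expectation-Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the conditional-independence graph of a multivariate
    stationary time series in the presence of hidden confounders. The observed
    process is modelled as the manifest block of a latent-variable vector
    autoregression whose inverse spectral density matrix is sparse in its
    manifest block; the sparsity pattern is recovered by an
    Expectation-Maximization scheme whose maximization steps are
    maximum-entropy covariance extension problems (log-determinant
    semidefinite programs solved in-package through their smooth duals).
    Candidate graphs produced along a regularization path are ranked by
    information-theoretic criteria (SBC, AICc, logFPE, RNML, EBIC and
    finite-dimensional extensions) or by relative-entropy score functions.
    A sparse-plus-low-rank baseline estimator is included for comparison,
    together with a synthetic-data generator and the simulation studies that
    validate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
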