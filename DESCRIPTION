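Package: fmap
Title: Gene Regulatory Network Reconstruction with Factor-Analytic Wishart Priors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a species-specific gene regulatory network from a
    small-sample expression matrix by Bayesian estimation of the Gaussian
    graphical model precision matrix. A conjugate Wishart prior is placed on
    the precision matrix and its scale hyperparameter is built from a
    maximum-likelihood factor analysis (fitted by EM, with the number of
    factors chosen by bi-cross-validation) of a related species' expression
    data, so that conserved co-expression structure informs the posterior.
    The closed-form posterior mode is sparsified by percentile
    hard-thresholding of partial correlations with the threshold chosen by
    the extended Bayesian information criterion, and the resulting network
    can be scored against a gold-standard edge list. A two-species
    latent-factor simulator and an end-to-end pipeline with a command-line
    interface are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
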