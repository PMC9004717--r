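Package: hcsurrogacy
Title: Surrogate Endpoint Evaluation with Havrda-Charvat Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic measures of association (ITMA) for
    surrogate-endpoint evaluation based on the Havrda-Charvat (Tsallis-type)
    entropy family. Provides closed-form generalized mutual information for
    bivariate Gaussian pairs, pairs of binary endpoints, and latent-probit
    binary/continuous pairs (including an Owen's-T form at order 2);
    maximum-likelihood univariate and bivariate probit regression; a
    longitudinal surrogacy pipeline that scores visit-schedule designs for a
    repeatedly measured continuous surrogate of a binary clinical endpoint
    and checks the Prentice conditional-independence criterion; and a
    synthetic clinical-trial generator for repeated-measures biomarker data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
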