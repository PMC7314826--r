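Package: endotype
Title: Mixed-Membership Phenotyping of Self-Tracked Endometriosis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised phenotyping of participant-generated self-tracking
    data with a multi-modal mixed-membership model: each participant's bag of
    categorical answers to a set of tracked questions is modelled as a mixture
    over latent phenotypes, each phenotype owning one categorical answer
    distribution per question. Provides a collapsed Gibbs sampler, a
    concatenated-vocabulary latent Dirichlet allocation baseline, left-to-right
    held-out log-likelihood estimation with a cross-validated hyperparameter
    grid, phenotype summarisation (hard assignments, top answers, answer-cloud
    weights, tracking-volume diagnostics), expert-agreement validation via
    confusion matrices and cluster purity, association screening against survey
    covariates, and a seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
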