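Package: psajoint
Title: Joint Bayesian Modelling of PSA Kinetics and PET-PSMA Positivity
Version: 0.1.0
Authors@R:
    person("psajoint", "developers", email = "psajoint@example.org",
           role = c("aut", "cre"))
Description: Hierarchical Bayesian joint model for post-prostatectomy
    prostate-specific antigen (PSA) kinetics and the probability of a
    positive PET-PSMA examination. The latent log-PSA trajectory declines
    linearly until a patient-specific change point and then follows a
    log-Gompertz growth curve towards an asymptote; PET-PSMA positivity is
    linked to the latent level through a logistic regression. Inference is
    by adaptive Metropolis-within-Gibbs MCMC with Polya-Gamma augmentation
    of the logistic block. The package also provides the posterior
    predictive estimator of the optimal time to recommend a PET-PSMA exam,
    synthetic-cohort generators, convergence diagnostics, credible-interval
    coverage tables, WAIC, ROC/AUC, leave-one-out predictive checks and
    simple clinical baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
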