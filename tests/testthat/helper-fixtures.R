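# Shared fixtures: everything is generated in code at test time.

# a small, well-behaved cohort for smoke tests (moderate noise so short
# chains behave)
tiny_design <- function(n = 5, seed = 11) {
  truth <- population_params(
    alpha_mu = c(-1, 0.1, 0.1, 0.1, 0.1, 0.1),
    alpha_gamma = c(-1.5, 0, 0, 0, 0, 0),
    alpha_beta = c(0.5, 0.2, 0.2, 0.2, 0.2, 0.2),
    beta1 = 2, beta2 = 0, psi_a = 2, w_mu = 0.3, w_gamma = 0.3,
    w_a = 0.5, a_sig2 = 12, b_sig2 = 1)
  sim_design(n_patients = n, truth = truth, lam_var = 1, seed = seed)
}

tiny_cohort <- function(n = 5, seed = 11) simulate_s1(tiny_design(n, seed))

quick_cfg <- function(n_iter = 800, burn_in = 400, thin = 4, seed = 5)
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)

# hand-assembled psa_draws object (for decision-layer fixtures): supply
# per-patient matrices of draws
fake_draws <- function(lam, lmu, lgam, a, tau, sig2,
                       alpha_beta, beta1, beta2, ids = NULL) {
  B <- nrow(lam); n <- ncol(lam)
  if (is.null(ids)) ids <- paste0("P", seq_len(n))
  one <- function(x) matrix(x, B, 1)
  p <- ncol(alpha_beta)
  structure(list(
    chains = list(list(
      lam = lam, lmu = lmu, lgam = lgam, a = a, tau = tau, sig2 = sig2,
      alpha_mu = matrix(0, B, 1), alpha_gamma = matrix(0, B, 1),
      alpha_beta = alpha_beta, beta1 = one(beta1), beta2 = one(beta2),
      psi_a = one(0), w_mu = one(1), w_gamma = one(1), w_a = one(1),
      a_sig2 = one(3), b_sig2 = one(2))),
    ids = ids, cfg = quick_cfg(), priors = prior_config(),
    accept = list(c(patient = 1)), n_patients = n),
    class = "psa_draws")
}

# inverse-gamma log-density, written independently of the package
ldinvgamma_oracle <- function(x, a, b) {
  dgamma(1 / x, shape = a, rate = b, log = TRUE) - 2 * log(x)
}
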