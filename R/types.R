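# Domain types. Plain validated lists with S3 classes, in the style of
# survival / lme4 control objects: cheap to build, strict on invariants.

#' One patient's observed series and covariates
#'
#' Container for a single patient: the irregular PSA series (ng/mL, strictly
#' positive, at strictly increasing times in months since prostatectomy),
#' the binary PET-PSMA series, and the three covariate vectors entering the
#' means of the decline rate, the growth rate and the logistic intercept.
#' Each covariate vector must start with an intercept entry equal to 1.
#'
#' @param patient_id scalar identifier (character or number).
#' @param psa_times,psa_values PSA measurement times (months, >= 0, strictly
#'   increasing) and levels (ng/mL, > 0). May be empty (length 0) for
#'   prior-only work, although the sampler requires at least one.
#' @param pet_times,pet_results PET-PSMA times (months, strictly increasing)
#'   and binary outcomes (0 = negative, 1 = positive). May be empty.
#' @param cov_mu,cov_gamma,cov_beta covariate vectors; first entry must be 1.
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, psa_times, psa_values,
                           pet_times = numeric(), pet_results = numeric(),
                           cov_mu = 1, cov_gamma = 1, cov_beta = 1) {
  stopifnot(length(patient_id) == 1L)
  psa_times <- as.numeric(psa_times); psa_values <- as.numeric(psa_values)
  pet_times <- as.numeric(pet_times); pet_results <- as.numeric(pet_results)
  if (length(psa_times) != length(psa_values))
    stop("psa_times and psa_values must have equal length")
  if (length(pet_times) != length(pet_results))
    stop("pet_times and pet_results must have equal length")
  if (any(psa_times < 0) || any(pet_times < 0))
    stop("all times must be >= 0 (months since prostatectomy)")
  if (length(psa_times) > 1 && any(diff(psa_times) <= 0))
    stop("psa_times must be strictly increasing")
  if (length(pet_times) > 1 && any(diff(pet_times) <= 0))
    stop("pet_times must be strictly increasing")
  if (any(psa_values <= 0))
    stop("psa_values must be strictly positive (ng/mL)")
  if (length(pet_results) && !all(pet_results %in% c(0, 1)))
    stop("pet_results must be binary (0/1)")
  for (nm in c("cov_mu", "cov_gamma", "cov_beta")) {
    v <- as.numeric(get(nm))
    if (length(v) < 1 || v[1] != 1)
      stop(nm, " must be non-empty with leading intercept entry 1")
    assign(nm, v)
  }
  structure(list(patient_id = patient_id,
                 psa_times = psa_times, psa_values = psa_values,
                 pet_times = pet_times, pet_results = pet_results,
                 cov_mu = cov_mu, cov_gamma = cov_gamma, cov_beta = cov_beta),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> id:", format(x$patient_id),
      "| PSA points:", length(x$psa_times),
      "| PET points:", length(x$pet_times), "\n")
  invisible(x)
}

#' Patient-level latent-curve parameters
#'
#' The six parameters of one patient's latent trajectory and noise:
#' intercept `lam` of log-PSA at surgery, decline slope `mu` (>= 0, per
#' month), change point `tau` (months), Gompertz rate `gamma` (>= 0, per
#' month), asymptote `a` of log-PSA (real-valued: a plateau below 1 ng/mL
#' corresponds to `a < 0`), and the observation variance `sigma2` on the
#' log scale.
#'
#' @param lam,mu,tau,gamma,a,sigma2 numeric scalars; see Description.
#' @return an object of class `trajectory_params`.
#' @export
trajectory_params <- function(lam, mu, tau, gamma, a, sigma2) {
  stopifnot(is.finite(lam), is.finite(a),
            mu >= 0, gamma >= 0, tau >= 0, sigma2 > 0)
  structure(list(lam = lam, mu = mu, tau = tau, gamma = gamma,
                 a = a, sigma2 = sigma2),
            class = "trajectory_params")
}

#' Population-level parameters
#'
#' Regression coefficients and random-effect hyperparameters shared across
#' patients: `alpha_mu`, `alpha_gamma`, `alpha_beta` are the coefficient
#' vectors for the means of log decline rate, log growth rate and the
#' logistic intercept; `beta1` and `beta2` are the effects of latent
#' log-PSA and of time on the logit of PET positivity; `psi_a` is the
#' common mean of the asymptote `a`; `w_mu`, `w_gamma`, `w_a` are random-effect
#' standard deviations; `a_sig2`, `b_sig2` are the shared inverse-gamma
#' shape and scale of the per-patient observation variances.
#'
#' @param alpha_mu,alpha_gamma,alpha_beta numeric coefficient vectors.
#' @param beta1,beta2 logistic-link coefficients.
#' @param psi_a mean of the log asymptote.
#' @param w_mu,w_gamma,w_a random-effect standard deviations (> 0).
#' @param a_sig2,b_sig2 inverse-gamma shape/scale (> 0) of sigma2.
#' @return an object of class `population_params`.
#' @export
population_params <- function(alpha_mu, alpha_gamma, alpha_beta,
                              beta1, beta2, psi_a,
                              w_mu, w_gamma, w_a, a_sig2, b_sig2) {
  stopifnot(w_mu > 0, w_gamma > 0, w_a > 0, a_sig2 > 0, b_sig2 > 0,
            is.finite(beta1), is.finite(beta2), is.finite(psi_a))
  structure(list(alpha_mu = as.numeric(alpha_mu),
                 alpha_gamma = as.numeric(alpha_gamma),
                 alpha_beta = as.numeric(alpha_beta),
                 beta1 = beta1, beta2 = beta2, psi_a = psi_a,
                 w_mu = w_mu, w_gamma = w_gamma, w_a = w_a,
                 a_sig2 = a_sig2, b_sig2 = b_sig2),
            class = "population_params")
}

#' Prior configuration
#'
#' Hyperprior settings. A Gaussian `N(0, normal_var)` prior is placed on
#' every regression coefficient, on each patient intercept `lam`, on the
#' log random-effect standard deviations `log(w_mu)`, `log(w_gamma)`, on
#' `psi_a`, and on the log mean and log variance of the observation
#' variance (the transformed scale of the inverse-gamma shape/scale, which
#' requires shape > 2). The random-effect variance of the asymptote gets an
#' inverse-gamma prior, and the change point a patient-specific mixed-type
#' prior: point masses `tau_endpoint_mass` on the first and last PSA times
#' and the remaining mass uniform on the inner observation window.
#'
#' @param normal_var variance of the Gaussian hyperpriors (default 100).
#' @param w_a_shape,w_a_scale inverse-gamma prior on `w_a^2` (default 1, 1).
#' @param tau_endpoint_mass prior mass on each endpoint of the change-point
#'   support (default 1/3).
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(normal_var = 100, w_a_shape = 1, w_a_scale = 1,
                         tau_endpoint_mass = 1 / 3) {
  stopifnot(normal_var > 0, w_a_shape > 0, w_a_scale > 0,
            tau_endpoint_mass >= 0, 2 * tau_endpoint_mass < 1)
  structure(list(normal_var = normal_var,
                 w_a_shape = w_a_shape, w_a_scale = w_a_scale,
                 tau_endpoint_mass = tau_endpoint_mass),
            class = "prior_config")
}

#' Design parameters of the optimal-time rule
#'
#' @param pi_star target probability of a positive PET-PSMA, in (0, 1).
#' @param rho posterior assurance level in (0, 1); default 0.95.
#' @param time_grid strictly increasing evaluation times (months). The
#'   default `NULL` lets [optimal_time()] build a 1-month grid from 0 to
#'   60 months past the patient's last observation.
#' @return an object of class `design_params`.
#' @export
design_params <- function(pi_star, rho = 0.95, time_grid = NULL) {
  stopifnot(pi_star > 0, pi_star < 1, rho > 0, rho < 1)
  if (!is.null(time_grid)) {
    time_grid <- as.numeric(time_grid)
    if (length(time_grid) > 1 && any(diff(time_grid) <= 0))
      stop("time_grid must be strictly increasing")
  }
  structure(list(pi_star = pi_star, rho = rho, time_grid = time_grid),
            class = "design_params")
}

#' MCMC configuration
#'
#' Defaults follow the published run lengths (150k iterations, 100k
#' burn-in, thinning 10); reduced values are appropriate for the simulation
#' studies bundled with the package.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in discarded iterations (< `n_iter`).
#' @param thin thinning stride (>= 1).
#' @param n_chains independent chains (>= 1; convergence diagnostics split
#'   single chains in half).
#' @param seed integer master seed; per-chain streams are derived from it.
#' @param adapt_target_mv,adapt_target_sc target acceptance rates of the
#'   adaptive random-walk proposals for multivariate blocks (0.234) and
#'   scalar updates (0.44).
#' @param adapt_decay Robbins-Monro decay exponent of the adaptation step.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 150000, burn_in = 100000, thin = 10,
                        n_chains = 1, seed = 1,
                        adapt_target_mv = 0.234, adapt_target_sc = 0.44,
                        adapt_decay = 0.6) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1,
            adapt_decay > 0, adapt_decay <= 1,
            adapt_target_mv > 0, adapt_target_mv < 1,
            adapt_target_sc > 0, adapt_target_sc < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 adapt_target_mv = adapt_target_mv,
                 adapt_target_sc = adapt_target_sc,
                 adapt_decay = adapt_decay),
            class = "mcmc_config")
}
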