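# Model core: latent trajectory, logistic link, observation likelihoods and
# prior densities. These are the pure functions every other layer builds on.

#' Latent log-PSA trajectory
#'
#' Piecewise trajectory of the latent log-PSA level: linear decline
#' `lam - mu * t` up to the change point `tau`, then log-Gompertz growth
#' `logx(tau) * e(t) + a * (1 - e(t))` with weight
#' `e(t) = exp(-gamma * (t - tau))`, where `logx(tau)` is the linear phase
#' evaluated at `tau` (the trajectory is continuous) and `a` is the
#' asymptote of log-PSA.
#'
#' @param p a [trajectory_params()] object.
#' @param t vector of evaluation times (months, >= 0).
#' @return numeric vector of latent log-PSA levels (log ng/mL).
#' @examples
#' p <- trajectory_params(lam = 2, mu = 0.1, tau = 10, gamma = 0.2,
#'                        a = 3, sigma2 = 0.1)
#' latent_log_psa(p, c(0, 10, 12))
#' @export
latent_log_psa <- function(p, t) {
  stopifnot(inherits(p, "trajectory_params"))
  if (any(t < 0)) stop("t must be >= 0")
  .latent_log_psa(p$lam, p$mu, p$tau, p$gamma, p$a, t)
}

# vectorised core: arguments recycle against each other (scalars against
# vectors); `a` is the asymptote on the natural scale of log-PSA.
.latent_log_psa <- function(lam, mu, tau, gamma, a, t) {
  n <- max(length(lam), length(mu), length(tau), length(gamma),
           length(a), length(t))
  lam <- rep_len(lam, n); mu <- rep_len(mu, n); tau <- rep_len(tau, n)
  gamma <- rep_len(gamma, n); a <- rep_len(a, n); t <- rep_len(t, n)
  lin <- lam - mu * t
  post <- t > tau
  if (any(post)) {
    e <- exp(-gamma[post] * (t[post] - tau[post]))
    lxt <- lam[post] - mu[post] * tau[post]
    lin[post] <- lxt * e + a[post] * (1 - e)
  }
  lin
}

#' Probability of a positive PET-PSMA examination
#'
#' Inverse-logit of `beta0 + beta1 * log_x + beta2 * t`: the logistic link
#' between the latent log-PSA level and the positivity probability. When
#' `beta1 > 0` the probability increases with the latent level and tends to
#' zero as the latent PSA tends to zero.
#'
#' @param log_x latent log-PSA level(s).
#' @param t time(s) in months.
#' @param beta0 patient-specific linear-predictor intercept.
#' @param beta1 effect of latent log-PSA.
#' @param beta2 linear time effect.
#' @return probabilities in `[0, 1]`.
#' @export
positive_prob <- function(log_x, t, beta0, beta1, beta2) {
  plogis(beta0 + beta1 * log_x + beta2 * t)
}

#' Gaussian log-likelihood of one PSA measurement
#'
#' The observed PSA is log-normally distributed around the latent level:
#' `log y ~ N(log_x, sigma2)`.
#'
#' @param y observed PSA (ng/mL, > 0).
#' @param log_x latent log-PSA level.
#' @param sigma2 observation variance on the log scale (> 0).
#' @return log-density value(s).
#' @export
loglik_psa_point <- function(y, log_x, sigma2) {
  if (any(y <= 0)) stop("y must be > 0")
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  dnorm(log(y), mean = log_x, sd = sqrt(sigma2), log = TRUE)
}

#' Bernoulli log-likelihood of one PET-PSMA result
#'
#' `z * log(pi) + (1 - z) * log(1 - pi)` with the convention
#' `0 * log 0 = 0`.
#'
#' @param z binary outcome(s), 0 or 1.
#' @param pi positivity probability(ies) in `[0, 1]`.
#' @return log-density value(s).
#' @export
loglik_pet_point <- function(z, pi) {
  if (!all(z %in% c(0, 1))) stop("z must be binary (0/1)")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  n <- max(length(z), length(pi))
  z <- rep_len(z, n); pi <- rep_len(pi, n)
  out <- numeric(n)
  out[z == 1] <- log(pi[z == 1])
  out[z == 0] <- log1p(-pi[z == 0])
  out
}

# numerically stable Bernoulli log-likelihood from the linear predictor
.loglik_pet_eta <- function(z, eta) {
  z * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# inverse-gamma log-density (shape a, scale b)
.ldinvgamma <- function(x, a, b) {
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}

# bijection between inverse-gamma (shape, scale) with shape > 2 and its
# (mean, variance): m = b/(a-1), v = b^2 / ((a-1)^2 (a-2)).
.sig2_moments_to_shape <- function(m, v) {
  a <- 2 + m^2 / v
  list(a = a, b = m * (a - 1))
}
.sig2_shape_to_moments <- function(a, b) {
  if (a <= 2) stop("shape must be > 2 for the moment parameterization")
  list(m = b / (a - 1), v = b^2 / ((a - 1)^2 * (a - 2)))
}

#' Mixed-type prior of the change point
#'
#' The change point of patient `i` is only identifiable inside the observed
#' PSA window: the prior puts point mass (default 1/3) on the first and on
#' the last PSA time, and spreads the remaining mass uniformly over
#' `[t_2, t_{J-1}]` (second to second-to-last PSA time). With fewer than
#' four PSA times the continuous part degenerates and the prior collapses,
#' with a warning, to equal masses on the first and last times.
#'
#' @param tau candidate change point(s), months.
#' @param psa_times the patient's PSA measurement times (sorted).
#' @param priors a [prior_config()] object.
#' @return log prior density (atoms on the counting measure, the middle on
#'   Lebesgue measure); `-Inf` outside the support.
#' @export
tau_log_prior <- function(tau, psa_times, priors = prior_config()) {
  J <- length(psa_times)
  if (J < 2) stop("need at least two PSA times for a change-point prior")
  pm <- priors$tau_endpoint_mass
  if (J < 4) {
    warning("fewer than 4 PSA times: change-point prior collapses to ",
            "atoms on the first and last PSA time")
    return(ifelse(tau == psa_times[1] | tau == psa_times[J], log(0.5), -Inf))
  }
  lo <- psa_times[2]; hi <- psa_times[J - 1]
  mid_mass <- 1 - 2 * pm
  out <- rep(-Inf, length(tau))
  out[tau == psa_times[1] | tau == psa_times[J]] <- log(pm)
  inside <- tau >= lo & tau <= hi
  out[inside] <- log(mid_mass) - log(hi - lo)
  out
}

# vectorised sampler from the mixed-type change-point prior, one draw per
# patient; lo/hi are the inner-window bounds, t1/tJ the endpoint atoms,
# degenerate flags patients with < 4 PSA times (atoms only).
.tau_prior_draw <- function(t1, lo, hi, tJ, degenerate, pm) {
  n <- length(t1)
  u <- runif(n)
  out <- numeric(n)
  atom1 <- u < pm
  atomJ <- u >= pm & u < 2 * pm
  mid <- !(atom1 | atomJ)
  out[atom1] <- t1[atom1]
  out[atomJ] <- tJ[atomJ]
  out[mid] <- runif(sum(mid), lo[mid], hi[mid])
  if (any(degenerate)) {
    d <- degenerate
    out[d] <- ifelse(runif(sum(d)) < 0.5, t1[d], tJ[d])
  }
  out
}

# mixed-type log prior, vectorised across patients
.tau_log_prior_vec <- function(tau, t1, lo, hi, tJ, degenerate, pm) {
  out <- rep(-Inf, length(tau))
  atom <- tau == t1 | tau == tJ
  out[atom] <- log(pm)
  inside <- !atom & tau >= lo & tau <= hi & !degenerate
  out[inside] <- log(1 - 2 * pm) - log((hi - lo)[inside])
  if (any(degenerate)) {
    d <- degenerate
    out[d] <- ifelse(tau[d] == t1[d] | tau[d] == tJ[d], log(0.5), -Inf)
  }
  out
}

#' Joint log-density of data, latent parameters and hyperparameters
#'
#' Sum of the factorized observation log-likelihood (Gaussian terms for the
#' observed log-PSA values, Bernoulli terms for the observed PET-PSMA
#' results), the random-effects log-densities of the patient-level
#' parameters, and the hyperprior log-densities. Transformed-scale priors
#' (on `log w_mu`, `log w_gamma` and the log mean/variance of the
#' observation-variance distribution) are evaluated on their sampling
#' scale, matching the MCMC target.
#'
#' @param data list of [patient_record()] objects (may be empty).
#' @param traj list of [trajectory_params()] objects, one per patient.
#' @param pop a [population_params()] object.
#' @param priors a [prior_config()] object.
#' @return scalar log-density (`-Inf` if any change point falls outside its
#'   prior support).
#' @export
joint_logdensity <- function(data, traj, pop, priors = prior_config()) {
  stopifnot(length(data) == length(traj))
  sdn <- sqrt(priors$normal_var)
  # hyperpriors
  lp <- sum(dnorm(c(pop$alpha_mu, pop$alpha_gamma, pop$alpha_beta,
                    pop$beta1, pop$beta2, pop$psi_a), 0, sdn, log = TRUE)) +
    dnorm(log(pop$w_mu), 0, sdn, log = TRUE) +
    dnorm(log(pop$w_gamma), 0, sdn, log = TRUE) +
    .ldinvgamma(pop$w_a^2, priors$w_a_shape, priors$w_a_scale)
  mo <- .sig2_shape_to_moments(pop$a_sig2, pop$b_sig2)
  lp <- lp + dnorm(log(mo$m), 0, sdn, log = TRUE) +
    dnorm(log(mo$v), 0, sdn, log = TRUE)
  for (i in seq_along(data)) {
    d <- data[[i]]; p <- traj[[i]]
    if (length(d$cov_mu) != length(pop$alpha_mu) ||
        length(d$cov_gamma) != length(pop$alpha_gamma) ||
        length(d$cov_beta) != length(pop$alpha_beta))
      stop("covariate/coefficient dimension mismatch for patient ",
           format(d$patient_id))
    # random effects
    lp <- lp + dnorm(p$lam, 0, sdn, log = TRUE) +
      dnorm(log(p$mu), sum(d$cov_mu * pop$alpha_mu), pop$w_mu, log = TRUE) +
      dnorm(log(p$gamma), sum(d$cov_gamma * pop$alpha_gamma), pop$w_gamma,
            log = TRUE) +
      dnorm(p$a, pop$psi_a, pop$w_a, log = TRUE) +
      .ldinvgamma(p$sigma2, pop$a_sig2, pop$b_sig2) +
      tau_log_prior(p$tau, d$psa_times, priors)
    # observation likelihood
    if (length(d$psa_times)) {
      lx <- latent_log_psa(p, d$psa_times)
      lp <- lp + sum(loglik_psa_point(d$psa_values, lx, p$sigma2))
    }
    if (length(d$pet_times)) {
      lxz <- latent_log_psa(p, d$pet_times)
      beta0 <- sum(d$cov_beta * pop$alpha_beta)
      eta <- beta0 + pop$beta1 * lxz + pop$beta2 * d$pet_times
      lp <- lp + sum(.loglik_pet_eta(d$pet_results, eta))
    }
  }
  lp
}
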