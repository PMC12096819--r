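# Adaptive Metropolis-within-Gibbs sampler.
#
# Update scheme per sweep:
#   (i)   per-patient curve parameters (lam, log mu, log gamma, a):
#         component-wise adaptive Gaussian random walks on the sampling
#         scales, one proposal scale per patient and component (target
#         acceptance 0.44) — the components live on very different scales,
#         so a common isotropic block proposal mixes poorly;
#   (ii)  change point tau: an independence proposal from its mixed-type
#         prior (atoms + uniform middle, so the Metropolis ratio reduces
#         to a likelihood ratio on the mixed support) followed by a
#         reflected Gaussian random walk restricted to interior states;
#   (iii) sigma2: conjugate inverse-gamma Gibbs given latent residuals;
#   (iv)  (alpha_beta, beta1, beta2): joint Gaussian Gibbs after
#         Polya-Gamma augmentation of every Bernoulli PET term;
#   (v)   alpha_mu, alpha_gamma, psi_a: conjugate Gaussian Gibbs;
#         w_mu, w_gamma: adaptive MH on the log scale; w_a^2: conjugate
#         inverse-gamma; (a_sig2, b_sig2): adaptive MH on the transformed
#         (log mean, log variance) scale.
# All patient-level updates are vectorised across patients (their full
# conditionals are independent given the population parameters).

#' Polya-Gamma random variates
#'
#' Draws from the Polya-Gamma distribution PG(b, c), used to augment the
#' Bernoulli PET-PSMA likelihood so the conditional of the logistic
#' coefficients is Gaussian. `E\[PG(b, c)\] = b / (2c) * tanh(c / 2)`.
#' Integer shapes use the exact Devroye rejection sampler; fractional
#' shapes a truncated convolution-of-gammas representation.
#'
#' @param n number of draws.
#' @param b shape(s), > 0 (recycled).
#' @param c tilt(s) (recycled).
#' @return numeric vector of `n` strictly positive draws.
#' @export
pg_draw <- function(n, b = 1, c = 0) {
  if (any(b <= 0)) stop("b must be > 0")
  pg_draw_cpp(as.integer(n), as.numeric(b), as.numeric(c))
}

#' One Robbins-Monro adaptation step
#'
#' Updates a random-walk proposal scale after a Metropolis decision:
#' `log(scale) <- log(scale) + iteration^(-adapt_decay) *
#' (accepted - target)`. The step size vanishes with the iteration index,
#' so adaptation is diminishing and the chain remains valid.
#'
#' @param scale current proposal standard deviation(s).
#' @param accepted acceptance indicator(s) (0/1, or a rate).
#' @param iteration iteration index (>= 1).
#' @param cfg an [mcmc_config()]; supplies the decay exponent.
#' @param target target acceptance rate.
#' @return updated scale(s).
#' @export
adapt_step <- function(scale, accepted, iteration, cfg = mcmc_config(),
                       target = cfg$adapt_target_sc) {
  stopifnot(iteration >= 1)
  scale * exp(iteration^(-cfg$adapt_decay) * (accepted - target))
}

# ---- internal data preparation ------------------------------------------

# per-patient sum of x grouped by patient index (length-n result)
.psum <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s
  }
  out
}

.prepare_data <- function(data) {
  n <- length(data)
  if (n == 0)
    return(list(n = 0L, ids = character(),
                ty = numeric(), ly = numeric(), iy = integer(),
                tz = numeric(), z = numeric(), iz = integer(),
                Cmu = matrix(0, 0, 1), Cg = matrix(0, 0, 1),
                Cb = matrix(0, 0, 1), n_psa = integer(),
                t1 = numeric(), lo = numeric(), hi = numeric(),
                tJ = numeric(), degenerate = logical()))
  stopifnot(all(vapply(data, inherits, TRUE, "patient_record")))
  n_psa <- vapply(data, function(d) length(d$psa_times), 1L)
  if (any(n_psa < 1)) stop("every patient needs at least one PSA value")
  pmu <- length(data[[1]]$cov_mu); pg <- length(data[[1]]$cov_gamma)
  pb <- length(data[[1]]$cov_beta)
  Cmu <- t(vapply(data, `[[`, numeric(pmu), "cov_mu"))
  Cg <- t(vapply(data, `[[`, numeric(pg), "cov_gamma"))
  Cb <- t(vapply(data, `[[`, numeric(pb), "cov_beta"))
  t1 <- vapply(data, function(d) d$psa_times[1], 1)
  tJ <- vapply(data, function(d) d$psa_times[length(d$psa_times)], 1)
  lo <- vapply(data, function(d)
    if (length(d$psa_times) >= 4) d$psa_times[2] else NA_real_, 1)
  hi <- vapply(data, function(d) {
    J <- length(d$psa_times)
    if (J >= 4) d$psa_times[J - 1] else NA_real_
  }, 1)
  degenerate <- n_psa < 4
  if (any(degenerate))
    warning(sum(degenerate), " patient(s) with fewer than 4 PSA times: ",
            "change-point prior collapses to the endpoint atoms")
  list(n = n,
       ids = vapply(data, function(d) as.character(d$patient_id), ""),
       ty = unlist(lapply(data, `[[`, "psa_times")),
       ly = log(unlist(lapply(data, `[[`, "psa_values"))),
       iy = rep(seq_len(n), n_psa),
       tz = unlist(lapply(data, `[[`, "pet_times")),
       z = unlist(lapply(data, `[[`, "pet_results")),
       iz = rep(seq_len(n), vapply(data, function(d)
         length(d$pet_times), 1L)),
       Cmu = Cmu, Cg = Cg, Cb = Cb, n_psa = n_psa,
       t1 = t1, lo = lo, hi = hi, tJ = tJ, degenerate = degenerate)
}

# patient-summed observation log-likelihood given patient-level parameters
# (on their sampling scales) and the logistic coefficients; returns the
# per-patient sums plus the latent levels needed by other blocks.
.obs_loglik <- function(pp, lam, lmu, lgam, la, tau, sig2, b0, b1, b2) {
  n <- pp$n
  mu <- exp(lmu); gam <- exp(lgam); a <- la
  lx_y <- .latent_log_psa(lam[pp$iy], mu[pp$iy], tau[pp$iy],
                          gam[pp$iy], a[pp$iy], pp$ty)
  ll_y <- dnorm(pp$ly, lx_y, sqrt(sig2[pp$iy]), log = TRUE)
  ll_y[!is.finite(ll_y)] <- -Inf
  out_y <- .psum(ll_y, pp$iy, n)
  if (length(pp$tz)) {
    lx_z <- .latent_log_psa(lam[pp$iz], mu[pp$iz], tau[pp$iz],
                            gam[pp$iz], a[pp$iz], pp$tz)
    eta <- b0[pp$iz] + b1 * lx_z + b2 * pp$tz
    ll_z <- .loglik_pet_eta(pp$z, eta)
    ll_z[!is.finite(ll_z)] <- -Inf
    out_z <- .psum(ll_z, pp$iz, n)
  } else {
    lx_z <- numeric(0); out_z <- numeric(n)
  }
  list(ll = out_y + out_z, lx_y = lx_y, lx_z = lx_z)
}

# Gaussian Gibbs draw for ridge-type conditionals:
# precision P = X'X / s2 + I / v0, mean P^{-1} X'y / s2
.ridge_draw <- function(X, y, s2, v0) {
  p <- ncol(X)
  if (nrow(X) == 0) return(rnorm(p, 0, sqrt(v0)))
  P <- crossprod(X) / s2 + diag(1 / v0, p)
  ch <- chol(P)
  m <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y) / s2))
  drop(m + backsolve(ch, rnorm(p)))
}

# weighted version for the Polya-Gamma block: precision X' Omega X + I/v0,
# mean P^{-1} X' kappa
.pg_coef_draw <- function(X, kappa, omega, v0) {
  p <- ncol(X)
  if (nrow(X) == 0) return(rnorm(p, 0, sqrt(v0)))
  P <- crossprod(X, X * omega) + diag(1 / v0, p)
  ch <- chol(P)
  m <- backsolve(ch, forwardsolve(t(ch), crossprod(X, kappa)))
  drop(m + backsolve(ch, rnorm(p)))
}

# data-driven deterministic initialization
.init_state <- function(pp, priors) {
  n <- pp$n
  lam <- mu0 <- tau <- numeric(n)
  la <- sig2 <- numeric(n)
  for (i in seq_len(n)) {
    sel <- pp$iy == i
    ty <- pp$ty[sel]; ly <- pp$ly[sel]
    J <- length(ty)
    h <- max(2L, ceiling(J / 2))
    f <- seq_len(min(h, J))
    slope <- if (J >= 2)
      stats::cov(ty[f], ly[f]) / max(stats::var(ty[f]), 1e-12) else 0
    # least-squares line on the first half of the series: its intercept
    # initialises lam, its negative slope (floored) the decline rate
    lam[i] <- if (J >= 2) mean(ly[f]) - slope * mean(ty[f]) else ly[1]
    mu0[i] <- max(-slope, 1e-3)
    tau[i] <- if (pp$degenerate[i]) pp$tJ[i] else
      min(max(median(ty), pp$lo[i]), pp$hi[i])
    la[i] <- ly[J]
    sig2[i] <- 1
  }
  list(lam = lam, lmu = log(mu0), lgam = rep(log(0.1), n), a = la,
       tau = tau, sig2 = sig2,
       amu = rep(0, ncol(pp$Cmu)), ag = rep(0, ncol(pp$Cg)),
       thb = rep(0, ncol(pp$Cb) + 2),  # (alpha_beta, beta1, beta2)
       psi_a = 0, lwmu = 0, lwg = 0, wa2 = 1, lm = 0, lv = 0)
}

# ---- main sampler --------------------------------------------------------

#' Sample the joint posterior by adaptive Metropolis-within-Gibbs
#'
#' Runs the MCMC described in the package vignette and returns thinned
#' post-burn-in draws of all patient-level parameters (`lam`, `log mu`,
#' `log gamma`, `a`, `tau`, `sigma2`) and population-level parameters
#' (`alpha_mu`, `alpha_gamma`, `alpha_beta`, `beta1`, `beta2`, `psi_a`,
#' `w_mu`, `w_gamma`, `w_a`, `a_sig2`, `b_sig2`). With an empty `data`
#' list the draws come from the hyperprior.
#'
#' @param data list of [patient_record()] objects.
#' @param priors a [prior_config()].
#' @param cfg an [mcmc_config()].
#' @param progress print progress every 10% of iterations.
#' @return an object of class `psa_draws`: a list with `chains` (per chain,
#'   matrices of kept draws), `ids`, `cfg`, `priors` and acceptance-rate
#'   bookkeeping.
#' @export
sample_posterior <- function(data, priors = prior_config(),
                             cfg = mcmc_config(), progress = FALSE) {
  pp <- .prepare_data(data)
  chains <- vector("list", cfg$n_chains)
  accept <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed((cfg$seed + 1009L * (ch - 1L)) %% 2147483647L)
    run <- .run_chain(pp, priors, cfg, progress)
    chains[[ch]] <- run$draws
    accept[[ch]] <- run$accept
  }
  structure(list(chains = chains, ids = pp$ids, cfg = cfg,
                 priors = priors, accept = accept,
                 n_patients = pp$n),
            class = "psa_draws")
}

.run_chain <- function(pp, priors, cfg, progress = FALSE) {
  n <- pp$n
  v0 <- priors$normal_var; sdn <- sqrt(v0)
  pm <- priors$tau_endpoint_mass
  st <- .init_state(pp, priors)
  pb2 <- length(st$thb)
  B <- (cfg$n_iter - cfg$burn_in) %/% cfg$thin
  keep <- function(nc) matrix(NA_real_, B, nc)
  dr <- list(lam = keep(n), lmu = keep(n), lgam = keep(n), a = keep(n),
             tau = keep(n), sig2 = keep(n),
             alpha_mu = keep(length(st$amu)), alpha_gamma = keep(length(st$ag)),
             alpha_beta = keep(pb2 - 2), beta1 = keep(1), beta2 = keep(1),
             psi_a = keep(1), w_mu = keep(1), w_gamma = keep(1),
             w_a = keep(1), a_sig2 = keep(1), b_sig2 = keep(1))
  # adaptive proposal scales: one per patient and curve component, one per
  # patient for the local change-point walk, scalars for the hyper blocks
  curve_fields <- c("lam", "lmu", "lgam", "a")
  s_pat <- matrix(rep(c(0.5, 0.3, 0.3, 0.5), each = n), n, 4,
                  dimnames = list(NULL, curve_fields))
  s_tau <- rep(1, n)
  s_wmu <- 0.3; s_wg <- 0.3; s_lm <- 0.3; s_lv <- 0.6
  acc <- c(patient = 0, joint = 0, tau = 0, w_mu = 0, w_gamma = 0,
           sig2_hyper = 0)
  kept <- 0L
  # adaptive-Metropolis joint move over (lam, lmu, lgam, a): running
  # per-patient mean and covariance (Andrieu-Thoms style), with the
  # proposal Cholesky refreshed periodically. The component-wise sweeps
  # handle scale; this move handles the strong (lam, mu) correlation.
  am_mean <- matrix(0, n, 4)
  am_cov <- array(0, c(n, 4, 4))
  if (n) {
    am_mean <- cbind(st$lam, st$lmu, st$lgam, st$a)
    for (j in 1:4) am_cov[, j, j] <- c(0.25, 0.09, 0.09, 0.25)[j]
  }
  am_L <- am_cov
  for (j in 1:4) am_L[, j, j] <- sqrt(am_cov[, j, j])
  s_am <- rep(2.38 / 2, n)
  am_refresh <- 25L
  # splice accepted per-patient proposals into the cached likelihood state
  splice <- function(cur, prop, ok) {
    cur$ll[ok] <- prop$ll[ok]
    sely <- ok[pp$iy]
    cur$lx_y[sely] <- prop$lx_y[sely]
    if (length(pp$tz)) {
      selz <- ok[pp$iz]
      cur$lx_z[selz] <- prop$lx_z[selz]
    }
    cur
  }
  for (it in seq_len(cfg$n_iter)) {
    wmu <- exp(st$lwmu); wg <- exp(st$lwg); wa <- sqrt(st$wa2)
    mmu <- if (n) drop(pp$Cmu %*% st$amu) else numeric(0)
    mg <- if (n) drop(pp$Cg %*% st$ag) else numeric(0)
    b0 <- if (n) drop(pp$Cb %*% st$thb[seq_len(pb2 - 2)]) else numeric(0)
    b1 <- st$thb[pb2 - 1]; b2 <- st$thb[pb2]
    if (n) {
      cur <- .obs_loglik(pp, st$lam, st$lmu, st$lgam, st$a, st$tau,
                         st$sig2, b0, b1, b2)
      # (i) patient curve parameters: component-wise adaptive MH ----------
      prior_of <- function(f, x) switch(f,
        lam = dnorm(x, 0, sdn, log = TRUE),
        lmu = dnorm(x, mmu, wmu, log = TRUE),
        lgam = dnorm(x, mg, wg, log = TRUE),
        a = dnorm(x, st$psi_a, wa, log = TRUE))
      for (f in curve_fields) {
        x <- st[[f]]
        x_p <- x + rnorm(n) * s_pat[, f]
        cand <- list(lam = st$lam, lmu = st$lmu, lgam = st$lgam, a = st$a)
        cand[[f]] <- x_p
        prop <- .obs_loglik(pp, cand$lam, cand$lmu, cand$lgam, cand$a,
                            st$tau, st$sig2, b0, b1, b2)
        lr <- prop$ll + prior_of(f, x_p) - cur$ll - prior_of(f, x)
        lr[!is.finite(lr)] <- -Inf
        ok <- log(runif(n)) < lr
        if (any(ok)) {
          st[[f]][ok] <- x_p[ok]
          cur <- splice(cur, prop, ok)
        }
        s_pat[, f] <- adapt_step(s_pat[, f], as.numeric(ok), it, cfg,
                                 cfg$adapt_target_sc)
        acc["patient"] <- acc["patient"] + mean(ok) / 4
      }
      # joint adaptive-Metropolis move over all four curve parameters,
      # proposal covariance learned per patient (captures the strong
      # intercept/slope correlation the component-wise sweeps miss)
      X <- cbind(st$lam, st$lmu, st$lgam, st$a)
      eps <- matrix(rnorm(4 * n), n, 4)
      step <- matrix(0, n, 4)
      for (j in 1:4) for (k in 1:j)
        step[, j] <- step[, j] + am_L[, j, k] * eps[, k]
      Xp <- X + s_am * step
      prop <- .obs_loglik(pp, Xp[, 1], Xp[, 2], Xp[, 3], Xp[, 4],
                          st$tau, st$sig2, b0, b1, b2)
      pr_c <- dnorm(X[, 1], 0, sdn, TRUE) + dnorm(X[, 2], mmu, wmu, TRUE) +
        dnorm(X[, 3], mg, wg, TRUE) + dnorm(X[, 4], st$psi_a, wa, TRUE)
      pr_p <- dnorm(Xp[, 1], 0, sdn, TRUE) + dnorm(Xp[, 2], mmu, wmu, TRUE) +
        dnorm(Xp[, 3], mg, wg, TRUE) + dnorm(Xp[, 4], st$psi_a, wa, TRUE)
      lr <- prop$ll + pr_p - cur$ll - pr_c
      lr[!is.finite(lr)] <- -Inf
      ok <- log(runif(n)) < lr
      if (any(ok)) {
        st$lam[ok] <- Xp[ok, 1]; st$lmu[ok] <- Xp[ok, 2]
        st$lgam[ok] <- Xp[ok, 3]; st$a[ok] <- Xp[ok, 4]
        cur <- splice(cur, prop, ok)
      }
      s_am <- adapt_step(s_am, as.numeric(ok), it, cfg,
                         cfg$adapt_target_mv)
      acc["joint"] <- acc["joint"] + mean(ok)
      # running per-patient moments of the curve parameters
      w_am <- it^(-cfg$adapt_decay)
      X <- cbind(st$lam, st$lmu, st$lgam, st$a)
      D <- X - am_mean
      am_mean <- am_mean + w_am * D
      for (j in 1:4) for (k in 1:j) {
        am_cov[, j, k] <- am_cov[, j, k] +
          w_am * (D[, j] * D[, k] - am_cov[, j, k])
        if (k < j) am_cov[, k, j] <- am_cov[, j, k]
      }
      if (it %% am_refresh == 0L) {
        for (i in seq_len(n)) {
          S <- am_cov[i, , ] + diag(1e-8, 4)
          ch <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch)) am_L[i, , ] <- t(ch)
        }
      }
      # (ii) change point: independence proposal from the mixed-type
      # prior (the Metropolis ratio reduces to a likelihood ratio), then
      # a reflected Gaussian random walk for interior states
      tau_p <- .tau_prior_draw(pp$t1, pp$lo, pp$hi, pp$tJ,
                               pp$degenerate, pm)
      prop <- .obs_loglik(pp, st$lam, st$lmu, st$lgam, st$a, tau_p,
                          st$sig2, b0, b1, b2)
      lr <- prop$ll - cur$ll
      lr[!is.finite(lr)] <- -Inf
      ok <- log(runif(n)) < lr
      if (any(ok)) {
        st$tau[ok] <- tau_p[ok]
        cur <- splice(cur, prop, ok)
      }
      acc["tau"] <- acc["tau"] + mean(ok) / 2
      interior <- !pp$degenerate & st$tau >= pp$lo & st$tau <= pp$hi
      if (any(interior)) {
        w2 <- pp$hi - pp$lo
        r <- (st$tau + rnorm(n) * s_tau - pp$lo) %% (2 * w2)
        tau_l <- pp$lo + pmin(r, 2 * w2 - r)   # reflect into [lo, hi]
        tau_l[!interior] <- st$tau[!interior]
        prop <- .obs_loglik(pp, st$lam, st$lmu, st$lgam, st$a, tau_l,
                            st$sig2, b0, b1, b2)
        lr <- prop$ll - cur$ll
        lr[!is.finite(lr) | !interior] <- -Inf
        ok <- log(runif(n)) < lr
        if (any(ok)) {
          st$tau[ok] <- tau_l[ok]
          cur <- splice(cur, prop, ok)
        }
        s_tau[interior] <- adapt_step(s_tau[interior],
                                      as.numeric(ok[interior]), it, cfg,
                                      cfg$adapt_target_sc)
        acc["tau"] <- acc["tau"] + mean(ok) / 2
      }
      # (iii) sigma2: conjugate inverse-gamma Gibbs ------------------------
      ssr <- .psum((pp$ly - cur$lx_y)^2, pp$iy, n)
      # blocked update of (a_sig2, b_sig2, sigma2): MH on the transformed
      # hyperparameters with sigma2 integrated out analytically (breaking
      # the funnel in which a collapsed sigma2 layer pins its own
      # hyper-variance at zero), then conjugate Gibbs for sigma2
      up <- .mh_sig2_hyper(st$lm, st$lv, pp$n_psa, ssr, s_lm, s_lv, sdn)
      st$lm <- up$lm; st$lv <- up$lv
      s_lm <- adapt_step(s_lm, up$acc_m, it, cfg, cfg$adapt_target_sc)
      s_lv <- adapt_step(s_lv, up$acc_v, it, cfg, cfg$adapt_target_sc)
      acc["sig2_hyper"] <- acc["sig2_hyper"] + (up$acc_m + up$acc_v) / 2
      ab <- .moments_to_ab(st$lm, st$lv)
      gp <- .sig2_gibbs_params(ab$a, ab$b, pp$n_psa, ssr)
      st$sig2 <- 1 / rgamma(n, shape = gp$shape, rate = gp$rate)
      # (iv) logistic block via Polya-Gamma augmentation -------------------
      if (length(pp$tz)) {
        X <- cbind(pp$Cb[pp$iz, , drop = FALSE], cur$lx_z, pp$tz)
        eta <- drop(X %*% st$thb)
        om <- pg_draw(length(eta), 1, eta)
        st$thb <- .pg_coef_draw(X, pp$z - 0.5, om, v0)
      } else {
        st$thb <- rnorm(pb2, 0, sdn)
      }
    } else {
      st$thb <- rnorm(pb2, 0, sdn)
    }
    # (v) hyperparameters -------------------------------------------------
    st$amu <- .ridge_draw(pp$Cmu, st$lmu, exp(2 * st$lwmu), v0)
    st$ag <- .ridge_draw(pp$Cg, st$lgam, exp(2 * st$lwg), v0)
    prec <- n / st$wa2 + 1 / v0
    st$psi_a <- rnorm(1, sum(st$a) / st$wa2 / prec, sqrt(1 / prec))
    mmu <- if (n) drop(pp$Cmu %*% st$amu) else numeric(0)
    mg <- if (n) drop(pp$Cg %*% st$ag) else numeric(0)
    up <- .mh_log_sd(st$lwmu, st$lmu, mmu, s_wmu, sdn)
    st$lwmu <- up$x
    s_wmu <- adapt_step(s_wmu, up$acc, it, cfg, cfg$adapt_target_sc)
    acc["w_mu"] <- acc["w_mu"] + up$acc
    up <- .mh_log_sd(st$lwg, st$lgam, mg, s_wg, sdn)
    st$lwg <- up$x
    s_wg <- adapt_step(s_wg, up$acc, it, cfg, cfg$adapt_target_sc)
    acc["w_gamma"] <- acc["w_gamma"] + up$acc
    st$wa2 <- 1 / rgamma(1, shape = priors$w_a_shape + n / 2,
                         rate = priors$w_a_scale +
                           sum((st$a - st$psi_a)^2) / 2)
    if (n == 0) {
      # prior-only walk for the observation-variance hyperparameters
      up <- .mh_sig2_hyper(st$lm, st$lv, integer(), numeric(),
                           s_lm, s_lv, sdn)
      st$lm <- up$lm; st$lv <- up$lv
      s_lm <- adapt_step(s_lm, up$acc_m, it, cfg, cfg$adapt_target_sc)
      s_lv <- adapt_step(s_lv, up$acc_v, it, cfg, cfg$adapt_target_sc)
      acc["sig2_hyper"] <- acc["sig2_hyper"] + (up$acc_m + up$acc_v) / 2
    }
    # ---- store ----------------------------------------------------------
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0) {
      kept <- kept + 1L
      ab <- .moments_to_ab(st$lm, st$lv)
      dr$lam[kept, ] <- st$lam; dr$lmu[kept, ] <- st$lmu
      dr$lgam[kept, ] <- st$lgam; dr$a[kept, ] <- st$a
      dr$tau[kept, ] <- st$tau; dr$sig2[kept, ] <- st$sig2
      dr$alpha_mu[kept, ] <- st$amu; dr$alpha_gamma[kept, ] <- st$ag
      dr$alpha_beta[kept, ] <- st$thb[seq_len(pb2 - 2)]
      dr$beta1[kept, 1] <- st$thb[pb2 - 1]; dr$beta2[kept, 1] <- st$thb[pb2]
      dr$psi_a[kept, 1] <- st$psi_a
      dr$w_mu[kept, 1] <- exp(st$lwmu); dr$w_gamma[kept, 1] <- exp(st$lwg)
      dr$w_a[kept, 1] <- sqrt(st$wa2)
      dr$a_sig2[kept, 1] <- ab$a; dr$b_sig2[kept, 1] <- ab$b
    }
    if (progress && it %% max(1L, cfg$n_iter %/% 10L) == 0L)
      message("iteration ", it, "/", cfg$n_iter)
  }
  list(draws = dr, accept = acc / cfg$n_iter)
}

.moments_to_ab <- function(lm, lv) .sig2_moments_to_shape(exp(lm), exp(lv))

# shape/rate of the conjugate inverse-gamma full conditional of sigma2
# given the residual sum of squares of n_i log-scale residuals
.sig2_gibbs_params <- function(a, b, n_obs, ssr) {
  list(shape = a + n_obs / 2, rate = b + ssr / 2)
}

# scalar MH step for a log random-effect SD with N(0, sdn^2) prior on the
# log scale. With data present |log sd| is capped at 10: when a small
# cohort lets the regression interpolate the random effects exactly
# (p >= n), the SD collapses towards 0 and the downstream ridge precision
# C'C / w^2 + I / v0 loses positive definiteness in floating point; the
# cap (w >= 4.5e-5, far below any estimable random-effect scale) keeps it
# well conditioned. Without data the prior is sampled untruncated.
.mh_log_sd <- function(lw, x, m, s, sdn) {
  cap <- if (length(x)) 10 else 700
  lw_p <- lw + rnorm(1) * s
  ll <- function(l) {
    if (abs(l) > cap) return(-Inf)
    sum(dnorm(x, m, exp(l), log = TRUE)) + dnorm(l, 0, sdn, log = TRUE)
  }
  lr <- ll(lw_p) - ll(lw)
  if (is.finite(lr) && log(runif(1)) < lr) list(x = lw_p, acc = 1)
  else list(x = lw, acc = 0)
}

# MH steps for the observation-variance hyperparameters on the
# transformed (log mean, log variance) scale, component-wise with
# separate adaptive scales. The per-patient variances are integrated out
# analytically: with sigma_i^2 ~ IG(a, b) and n_i Gaussian residuals with
# sum of squares ssr_i, the marginal contribution of patient i is
#   a log b - log Gamma(a) + log Gamma(a + n_i/2)
#     - (a + n_i/2) log(b + ssr_i/2)
# (Gaussian constants drop). Updating (a, b) against this marginal and
# then redrawing sigma2 from its conjugate conditional is a valid blocked
# update and avoids the funnel where a collapsed sigma2 layer pins its
# own hyper-variance at zero.
.mh_sig2_hyper <- function(lm, lv, n_obs, ssr, s_lm, s_lv, sdn) {
  ll <- function(lm, lv) {
    # cap the transformed support: beyond |50| the shape/scale overflow
    # and the marginal is numerically meaningless (prior mass ~ 0 there)
    if (abs(lm) > 50 || abs(lv) > 50) return(-Inf)
    ab <- .moments_to_ab(lm, lv)
    a <- ab$a; b <- ab$b
    h <- n_obs / 2; s <- ssr / 2
    # lgamma(a + h) - lgamma(a) loses all precision for huge shapes;
    # the midpoint digamma form is exact to O(h^3 psi''(a))
    lgd <- if (a > 1e8) h * digamma(a + h / 2)
           else lgamma(a + h) - lgamma(a)
    # a log b - (a + h) log(b + s) = -a log1p(s/b) - h log(b + s)
    sum(-a * log1p(s / b) - h * log(b + s) + lgd) +
      dnorm(lm, 0, sdn, log = TRUE) + dnorm(lv, 0, sdn, log = TRUE)
  }
  cur <- ll(lm, lv)
  acc_m <- 0; acc_v <- 0
  lm_p <- lm + rnorm(1) * s_lm
  new <- ll(lm_p, lv)
  if (is.finite(new - cur) && log(runif(1)) < new - cur) {
    lm <- lm_p; cur <- new; acc_m <- 1
  }
  lv_p <- lv + rnorm(1) * s_lv
  new <- ll(lm, lv_p)
  if (is.finite(new - cur) && log(runif(1)) < new - cur) {
    lv <- lv_p; acc_v <- 1
  }
  list(lm = lm, lv = lv, acc_m = acc_m, acc_v = acc_v)
}

# ---- draws utilities -----------------------------------------------------

#' @export
print.psa_draws <- function(x, ...) {
  B <- nrow(x$chains[[1]]$lam)
  cat("<psa_draws>", length(x$chains), "chain(s) x", B, "kept draws,",
      x$n_patients, "patients\n")
  cat("mean acceptance rates:\n")
  print(round(Reduce(`+`, x$accept) / length(x$accept), 3))
  invisible(x)
}

# pooled draws of one parameter family across chains (B_total x k matrix)
.pool <- function(draws, name) {
  do.call(rbind, lapply(draws$chains, `[[`, name))
}

# patient column index inside a psa_draws object
.patient_index <- function(draws, patient_id) {
  i <- match(as.character(patient_id), draws$ids)
  if (is.na(i)) stop("patient ", format(patient_id), " absent from draws")
  i
}

#' Impute unobserved measurements from posterior draws
#'
#' For each kept draw and each patient, samples the PSA value at the PET
#' times from the log-normal observation model, and the PET result at the
#' PSA times from the Bernoulli model. The factorized likelihood makes
#' these conditionally independent of the data given the parameters.
#'
#' @param draws a `psa_draws` object.
#' @param data the list of [patient_record()] objects used in the fit.
#' @return a list, one element per patient, each with matrices `y_u`
#'   (draws x PET times) and `z_u` (draws x PSA times).
#' @export
impute_unobserved <- function(draws, data) {
  lam <- .pool(draws, "lam"); lmu <- .pool(draws, "lmu")
  lgam <- .pool(draws, "lgam"); la <- .pool(draws, "a")
  tau <- .pool(draws, "tau"); sig2 <- .pool(draws, "sig2")
  ab <- .pool(draws, "alpha_beta")
  b1 <- drop(.pool(draws, "beta1")); b2 <- drop(.pool(draws, "beta2"))
  out <- vector("list", length(data))
  names(out) <- draws$ids
  for (i in seq_along(data)) {
    d <- data[[i]]
    j <- .patient_index(draws, d$patient_id)
    B <- nrow(lam)
    y_u <- matrix(NA_real_, B, length(d$pet_times))
    z_u <- matrix(NA_integer_, B, length(d$psa_times))
    if (length(d$pet_times)) {
      for (b in seq_len(B)) {
        lx <- .latent_log_psa(lam[b, j], exp(lmu[b, j]), tau[b, j],
                              exp(lgam[b, j]), la[b, j], d$pet_times)
        y_u[b, ] <- exp(lx + rnorm(length(lx), 0, sqrt(sig2[b, j])))
      }
    }
    if (length(d$psa_times)) {
      beta0 <- drop(ab %*% d$cov_beta)
      for (b in seq_len(B)) {
        lx <- .latent_log_psa(lam[b, j], exp(lmu[b, j]), tau[b, j],
                              exp(lgam[b, j]), la[b, j], d$psa_times)
        pi <- positive_prob(lx, d$psa_times, beta0[b], b1[b], b2[b])
        z_u[b, ] <- rbinom(length(pi), 1, pi)
      }
    }
    out[[i]] <- list(y_u = y_u, z_u = z_u)
  }
  out
}

#' Per-draw, per-observation log-likelihoods
#'
#' Evaluates the observation log-likelihood of every recorded measurement
#' (PSA and PET) under every kept posterior draw; the input of [waic()]
#' and of the importance-weighted cross-validation in
#' [loocv_predictive()].
#'
#' @param draws a `psa_draws` object.
#' @param data the fitted list of [patient_record()] objects.
#' @return list with matrix `ll` (draws x observations) and a data frame
#'   `obs` describing each column (patient, type, time, value).
#' @export
pointwise_loglik <- function(draws, data) {
  pp <- .prepare_data(data)
  lam <- .pool(draws, "lam"); lmu <- .pool(draws, "lmu")
  lgam <- .pool(draws, "lgam"); la <- .pool(draws, "a")
  tau <- .pool(draws, "tau"); sig2 <- .pool(draws, "sig2")
  abm <- .pool(draws, "alpha_beta")
  b1 <- drop(.pool(draws, "beta1")); b2 <- drop(.pool(draws, "beta2"))
  B <- nrow(lam)
  m_y <- length(pp$ty); m_z <- length(pp$tz)
  ll <- matrix(NA_real_, B, m_y + m_z)
  for (b in seq_len(B)) {
    lx_y <- .latent_log_psa(lam[b, pp$iy], exp(lmu[b, pp$iy]),
                            tau[b, pp$iy], exp(lgam[b, pp$iy]),
                            la[b, pp$iy], pp$ty)
    ll[b, seq_len(m_y)] <- dnorm(pp$ly, lx_y, sqrt(sig2[b, pp$iy]),
                                 log = TRUE)
    if (m_z) {
      lx_z <- .latent_log_psa(lam[b, pp$iz], exp(lmu[b, pp$iz]),
                              tau[b, pp$iz], exp(lgam[b, pp$iz]),
                              la[b, pp$iz], pp$tz)
      beta0 <- drop(pp$Cb[pp$iz, , drop = FALSE] %*% abm[b, ])
      eta <- beta0 + b1[b] * lx_z + b2[b] * pp$tz
      ll[b, m_y + seq_len(m_z)] <- .loglik_pet_eta(pp$z, eta)
    }
  }
  obs <- data.frame(
    patient = c(pp$ids[pp$iy], pp$ids[pp$iz]),
    type = rep(c("psa", "pet"), c(m_y, m_z)),
    time = c(pp$ty, pp$tz),
    value = c(exp(pp$ly), pp$z))
  list(ll = ll, obs = obs)
}
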