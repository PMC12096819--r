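test_that("Polya-Gamma draws match known moment identities", {
  set.seed(101)
  pg_mean <- function(b, c) if (c == 0) b / 4 else b / (2 * c) * tanh(c / 2)
  for (bc in list(c(1, 0), c(1, 2), c(3, 1), c(2.5, 0.5))) {
    x <- pg_draw(2e4, bc[1], bc[2])
    expect_true(all(x > 0))
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - pg_mean(bc[1], bc[2])), 4 * se)
  }
  expect_error(pg_draw(1, b = 0), "b must be")
  # reproducible under set.seed
  set.seed(7); a1 <- pg_draw(10, 1, 1)
  set.seed(7); a2 <- pg_draw(10, 1, 1)
  expect_identical(a1, a2)
})

test_that("Robbins-Monro adaptation has the documented fixed point", {
  cfg <- mcmc_config(n_iter = 100, burn_in = 10, adapt_decay = 0.6)
  # accepted exactly at the target rate leaves the scale unchanged
  expect_equal(adapt_step(0.5, cfg$adapt_target_sc, 3, cfg), 0.5)
  # always-reject stream strictly decreases the scale
  s <- 1
  for (k in 1:20) {
    s_new <- adapt_step(s, 0, k, cfg)
    expect_lt(s_new, s)
    s <- s_new
  }
  # step size at iteration k is k^(-decay) on the log scale
  expect_equal(log(adapt_step(1, 1, 9, cfg)),
               9^(-0.6) * (1 - cfg$adapt_target_sc))
})

test_that("sigma2 Gibbs conditional matches a quadrature-normalized oracle", {
  # fixed residuals; conditional should be IG(a + n/2, b + ssr/2)
  set.seed(3)
  r <- rnorm(12, 0, 0.8)
  a <- 3; b <- 2
  gp <- psajoint:::.sig2_gibbs_params(a, b, length(r), sum(r^2))
  expect_equal(gp$shape, a + 6)
  expect_equal(gp$rate, b + sum(r^2) / 2)
  # oracle: normalize prior x likelihood numerically and compare densities
  log_post_unnorm <- function(s2)
    ldinvgamma_oracle(s2, a, b) +
      vapply(s2, function(v) sum(dnorm(r, 0, sqrt(v), log = TRUE)), 1)
  Z <- integrate(function(s2) exp(log_post_unnorm(s2)), 0, Inf,
                 rel.tol = 1e-13)$value
  grid <- c(0.2, 0.5, 1, 2, 5)
  d_oracle <- exp(log_post_unnorm(grid)) / Z
  d_pkg <- exp(ldinvgamma_oracle(grid, gp$shape, gp$rate))
  expect_equal(d_pkg, d_oracle, tolerance = 1e-10)
})

test_that("with no data the posterior reproduces the hyperprior", {
  dr <- sample_posterior(list(), prior_config(),
                         mcmc_config(n_iter = 6000, burn_in = 1000,
                                     thin = 1, seed = 3))
  ab <- do.call(rbind, lapply(dr$chains, `[[`, "alpha_beta"))[, 1]
  # alpha_beta is a direct Gibbs draw from N(0, 100) when no PET data
  expect_lt(abs(mean(ab)), 4 * 10 / sqrt(length(ab)))
  expect_lt(abs(sd(ab) / 10 - 1), 0.1)
  b1 <- drop(do.call(rbind, lapply(dr$chains, `[[`, "beta1")))
  expect_lt(abs(sd(b1) / 10 - 1), 0.1)
  # w_a^2 ~ IG(1,1): median is 1/qgamma(0.5, 1, 1) = 1/log(2)
  wa2 <- drop(do.call(rbind, lapply(dr$chains, `[[`, "w_a")))^2
  expect_lt(abs(median(wa2) - 1 / log(2)), 0.25)
})

test_that("the change-point kernel targets its full conditional (quadrature)", {
  # freeze every parameter except tau for one patient and iterate the
  # package's two tau moves; compare the long-run distribution with a
  # deterministic quadrature of prior x likelihood over the mixed support
  set.seed(9)
  d <- patient_record("q", psa_times = c(1, 4, 8, 12, 16, 20),
                      psa_values = exp(c(1.8, 1.1, 0.4, 0.9, 1.9, 2.6)))
  pp <- psajoint:::.prepare_data(list(d))
  lam <- 2.1; lmu <- log(0.21); lgam <- log(0.25); a <- 3.2; sig2 <- 0.4
  llik <- function(tau)
    psajoint:::.obs_loglik(pp, lam, lmu, lgam, a, tau, sig2,
                           0, 0, 0)$ll
  # quadrature over the continuous part + the two atoms
  lo <- 4; hi <- 16
  f_mid <- function(tau) vapply(tau, function(t)
    exp(llik(t) + log(1 / 3) - log(hi - lo)), 1)
  Zmid <- integrate(f_mid, lo, hi, rel.tol = 1e-10)$value
  w_atoms <- exp(llik(1) + log(1 / 3)) + exp(llik(20) + log(1 / 3))
  Z <- Zmid + w_atoms
  # run the kernel
  n_it <- 20000
  tau <- 8; out <- numeric(n_it)
  for (it in seq_len(n_it)) {
    tp <- psajoint:::.tau_prior_draw(pp$t1, pp$lo, pp$hi, pp$tJ,
                                     pp$degenerate, 1 / 3)
    if (log(runif(1)) < llik(tp) - llik(tau)) tau <- tp
    if (tau >= lo && tau <= hi) {
      w2 <- hi - lo
      r <- (tau + rnorm(1) * 1.5 - lo) %% (2 * w2)
      tl <- lo + min(r, 2 * w2 - r)
      if (log(runif(1)) < llik(tl) - llik(tau)) tau <- tl
    }
    out[it] <- tau
  }
  out <- out[-(1:2000)]
  # atom mass and CDF of the continuous part
  p_atom1 <- exp(llik(1) + log(1 / 3)) / Z
  expect_lt(abs(mean(out == 1) - p_atom1), 0.03)
  for (q in c(6, 9, 12, 15)) {
    p_q <- (integrate(f_mid, lo, q, rel.tol = 1e-10)$value +
              exp(llik(1) + log(1 / 3))) / Z
    expect_lt(abs(mean(out <= q) - p_q), 0.04)
  }
})

test_that("posterior recovery on a dense low-noise patient", {
  set.seed(14)
  ty <- seq(1, 25, by = 0.5)
  truth <- trajectory_params(lam = 2, mu = 0.3, tau = 10, gamma = 0.4,
                             a = 6, sigma2 = 1e-4)
  y <- exp(latent_log_psa(truth, ty) + rnorm(length(ty), 0, 1e-2))
  rec <- patient_record("X", ty, y)
  dr <- sample_posterior(list(rec), prior_config(),
                         mcmc_config(n_iter = 6000, burn_in = 3000,
                                     thin = 3, seed = 2))
  post <- function(nm) do.call(rbind, lapply(dr$chains, `[[`, nm))[, 1]
  for (par in list(c("lam", 2), c("tau", 10))) {
    x <- post(par[1])
    expect_lt(abs(mean(x) - as.numeric(par[2])), 3 * max(sd(x), 1e-3))
  }
  x <- post("lmu")
  expect_lt(abs(mean(x) - log(0.3)), 3 * max(sd(x), 1e-3))
})

test_that("imputation of unobserved measurements follows the model", {
  # hand-built degenerate draws: sigma2 -> 0 forces imputed log-PSA to the
  # latent curve; a huge positive linear predictor forces imputed PET to 1
  B <- 40
  dr <- fake_draws(lam = matrix(1, B, 1), lmu = matrix(log(0.1), B, 1),
                   lgam = matrix(log(0.3), B, 1), a = matrix(4, B, 1),
                   tau = matrix(6, B, 1), sig2 = matrix(1e-20, B, 1),
                   alpha_beta = matrix(50, B, 1), beta1 = rep(0, B),
                   beta2 = rep(0, B), ids = "P1")
  d <- patient_record("P1", psa_times = c(2, 4, 8), psa_values = c(1, 1, 2),
                      pet_times = c(10, 12), pet_results = c(1, 1))
  set.seed(2)
  imp <- impute_unobserved(dr, list(d))
  tp <- trajectory_params(1, 0.1, 6, 0.3, a = 4, sigma2 = 1e-20)
  expect_equal(log(imp$P1$y_u[1, ]), latent_log_psa(tp, c(10, 12)),
               tolerance = 1e-6)
  expect_true(all(imp$P1$z_u == 1))   # beta0 = 50 => pi = 1
  # law of total expectation: mean imputed z tracks the mean of pi
  dr2 <- fake_draws(lam = matrix(1, B, 1), lmu = matrix(log(0.1), B, 1),
                    lgam = matrix(log(0.3), B, 1), a = matrix(4, B, 1),
                    tau = matrix(6, B, 1), sig2 = matrix(0.2, B, 1),
                    alpha_beta = matrix(rnorm(B, 0, 1), B, 1),
                    beta1 = rep(0.5, B), beta2 = rep(0, B), ids = "P1")
  set.seed(3)
  imp2 <- impute_unobserved(dr2, list(d))
  cv <- predictive_curves(dr2, d, grid = d$psa_times)
  expect_lt(abs(mean(imp2$P1$z_u) - mean(cv$pi)), 0.08)
})

test_that("pointwise log-likelihood matrix matches direct evaluation", {
  sim <- tiny_cohort(3, seed = 21)
  dr <- sample_posterior(sim$records, prior_config(), quick_cfg())
  pw <- pointwise_loglik(dr, sim$records)
  expect_equal(nrow(pw$obs),
               sum(vapply(sim$records, function(d)
                 length(d$psa_times) + length(d$pet_times), 1L)))
  expect_equal(ncol(pw$ll), nrow(pw$obs))
  # spot check one PSA entry against loglik_psa_point at draw 1
  d1 <- sim$records[[1]]
  lam <- do.call(rbind, lapply(dr$chains, `[[`, "lam"))[1, 1]
  lmu <- do.call(rbind, lapply(dr$chains, `[[`, "lmu"))[1, 1]
  lgam <- do.call(rbind, lapply(dr$chains, `[[`, "lgam"))[1, 1]
  a <- do.call(rbind, lapply(dr$chains, `[[`, "a"))[1, 1]
  tau <- do.call(rbind, lapply(dr$chains, `[[`, "tau"))[1, 1]
  s2 <- do.call(rbind, lapply(dr$chains, `[[`, "sig2"))[1, 1]
  tp <- trajectory_params(lam, exp(lmu), tau, exp(lgam), a, s2)
  expect_equal(pw$ll[1, 1],
               loglik_psa_point(d1$psa_values[1],
                                latent_log_psa(tp, d1$psa_times[1]), s2))
})

test_that("sampler bookkeeping: kept draws, support, reproducibility", {
  sim <- tiny_cohort(4, seed = 31)
  cfg <- quick_cfg(n_iter = 600, burn_in = 200, thin = 4, seed = 9)
  dr <- sample_posterior(sim$records, prior_config(), cfg)
  B <- (cfg$n_iter - cfg$burn_in) %/% cfg$thin
  expect_equal(nrow(dr$chains[[1]]$lam), B)
  expect_equal(ncol(dr$chains[[1]]$tau), 4)
  # stored draws respect the parameter supports
  expect_true(all(dr$chains[[1]]$sig2 > 0))
  expect_true(all(dr$chains[[1]]$w_mu > 0))
  expect_true(all(dr$chains[[1]]$a_sig2 > 2))
  for (i in 1:4) {
    ty <- sim$records[[i]]$psa_times
    tau_i <- dr$chains[[1]]$tau[, i]
    J <- length(ty)
    ok <- tau_i == ty[1] | tau_i == ty[J] |
      (tau_i >= ty[2] & tau_i <= ty[J - 1])
    expect_true(all(ok))
  }
  # same config + seed => identical draws
  dr2 <- sample_posterior(sim$records, prior_config(), cfg)
  expect_identical(dr$chains, dr2$chains)
  # two chains give two sets of draws
  cfg2 <- quick_cfg(n_iter = 300, burn_in = 100, thin = 2, seed = 9)
  cfg2$n_chains <- 2L
  dr3 <- sample_posterior(sim$records, prior_config(), cfg2)
  expect_length(dr3$chains, 2)
  expect_false(identical(dr3$chains[[1]]$lam, dr3$chains[[2]]$lam))
})
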