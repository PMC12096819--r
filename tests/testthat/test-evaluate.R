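test_that("R-hat behaves at its known reference points", {
  set.seed(5)
  x <- rnorm(2000)
  expect_equal(rhat(cbind(x, x)), 1, tolerance = 1e-3)
  # disjoint chains: between-variance dominates; compare to the direct
  # formula computed independently
  c1 <- rnorm(1000); c2 <- rnorm(1000, 100)
  m <- cbind(c1, c2)
  W <- (var(c1) + var(c2)) / 2
  B <- 1000 * var(c(mean(c1), mean(c2)))
  oracle <- sqrt(((999 / 1000) * W + B / 1000) / W)
  expect_equal(rhat(m), oracle, tolerance = 1e-12)
  expect_gt(rhat(m), 10)
  # permutation within chains leaves the statistic unchanged
  mp <- cbind(sample(c1), sample(c2))
  expect_equal(rhat(mp), rhat(m), tolerance = 1e-12)
  # zero-variance chains are defined as 1
  expect_equal(rhat(cbind(rep(2, 10), rep(2, 10))), 1)
  # a single vector is split in half
  expect_gt(rhat(c(rnorm(500), rnorm(500, 50))), 5)
})

test_that("coverage table counts interval hits exactly", {
  B <- 200; n <- 5
  truth <- lapply(1:n, function(i)
    trajectory_params(lam = i, mu = 0.1, tau = 5, gamma = 0.2, a = 2,
                      sigma2 = 0.5))
  base <- function(center) {
    m <- sapply(center, function(c) c + seq(-0.5, 0.5, length.out = B))
    m
  }
  # tau intervals cover the truth (5) for exactly 3 of 5 patients
  tau_centers <- c(5, 5, 5, 8, 9)
  dr <- fake_draws(lam = base(1:n), lmu = base(rep(log(0.1), n)),
                   lgam = base(rep(log(0.2), n)), a = base(rep(2, n)),
                   tau = base(tau_centers), sig2 = base(rep(0.5, n)),
                   alpha_beta = matrix(0, B, 1), beta1 = rep(1, B),
                   beta2 = rep(0, B))
  ct <- coverage_table(dr, truth)
  expect_s3_class(ct, "coverage_report")
  expect_equal(ct$coverage_pct[ct$parameter == "tau"], 60)
  expect_equal(ct$coverage_pct[ct$parameter == "lam"], 100)
  expect_true(all(ct$ciw_mean >= 0))
  # point-mass draws at the truth: full coverage, zero widths
  pm <- function(v) matrix(rep(v, each = B), B, n)
  drp <- fake_draws(lam = pm(1:n), lmu = pm(rep(log(0.1), n)),
                    lgam = pm(rep(log(0.2), n)), a = pm(rep(2, n)),
                    tau = pm(rep(5, n)), sig2 = pm(rep(0.5, n)),
                    alpha_beta = matrix(0, B, 1), beta1 = rep(1, B),
                    beta2 = rep(0, B))
  ctp <- coverage_table(drp, truth)
  expect_true(all(ctp$coverage_pct == 100))
  expect_true(all(ctp$ciw_mean == 0))
  # draws far from the truth: zero coverage
  drf <- fake_draws(lam = pm(1:n + 100), lmu = pm(rep(5, n)),
                    lgam = pm(rep(5, n)), a = pm(rep(50, n)),
                    tau = pm(rep(20, n)), sig2 = pm(rep(99, n)),
                    alpha_beta = matrix(0, B, 1), beta1 = rep(1, B),
                    beta2 = rep(0, B))
  expect_true(all(coverage_table(drf, truth)$coverage_pct == 0))
  expect_error(coverage_table(dr, truth[1:3]), "mismatch")
})

test_that("WAIC follows its defining identities", {
  # identical draws: p_waic = 0, waic = -2 * sum(loglik)
  ll <- matrix(rep(c(-1.2, -0.4, -2), each = 3), nrow = 3)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll[1, ]))
  # 2-draw, 1-observation fixture by hand
  ll2 <- matrix(c(-1, -2), 2, 1)
  w2 <- waic(ll2)
  lppd <- log(mean(exp(c(-1, -2))))
  expect_equal(w2$lppd, lppd)
  expect_equal(w2$p_waic, var(c(-1, -2)))
  expect_equal(w2$waic, -2 * (lppd - var(c(-1, -2))))
  # adding an observation with constant loglik c shifts waic by -2c
  cns <- -0.7
  w3 <- waic(cbind(ll2, c(cns, cns)))
  expect_equal(w3$waic, w2$waic - 2 * cns)
  expect_error(waic(ll2[1, , drop = FALSE]), ">= 2 draws")
})

test_that("WAIC prefers the generating model over a misspecified one", {
  # well-specified pointwise likelihoods vs a variance-inflated rival,
  # repeated over seeds; the generating model should win most runs
  wins <- 0
  for (seed in 1:7) {
    set.seed(seed)
    y <- rnorm(40)
    draws_mu <- rnorm(400, mean(y), sd = 1 / sqrt(40))
    ll_good <- sapply(y, function(yi) dnorm(yi, draws_mu, 1, log = TRUE))
    ll_bad <- sapply(y, function(yi) dnorm(yi, draws_mu + 1.5, 3,
                                           log = TRUE))
    if (waic(ll_good)$waic < waic(ll_bad)$waic) wins <- wins + 1
  }
  expect_gte(wins, 6)
})

test_that("ROC/AUC agree with the Mann-Whitney construction", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), "both label classes")
  # trapezoid AUC == Mann-Whitney U / (n1 n0) on tie-free fixtures
  set.seed(44)
  for (k in 1:10) {
    sc <- sample(seq(0.01, 0.99, by = 0.01), 30)
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    u <- mean(outer(sc[lb == 1], sc[lb == 0], ">"))
    expect_equal(roc_auc(sc, lb)$auc, u, tolerance = 1e-12)
  }
  # closest-to-(0,1) threshold on a clean fixture
  r2 <- roc_auc(c(0.1, 0.2, 0.6, 0.7, 0.9), c(0, 0, 1, 1, 1))
  expect_equal(r2$best_threshold, 0.6)
})

test_that("classification metrics match the confusion counts", {
  cr <- classification_report(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0))
  expect_equal(cr$accuracy, 1)
  expect_equal(cr$balanced_accuracy, 1)
  # all-positive predictions on balanced labels
  cr2 <- classification_report(rep(0.9, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(cr2$balanced_accuracy, 0.5)
  # fixture with TP=3, TN=1, FP=1, FN=1
  probs <- c(0.9, 0.9, 0.9, 0.2, 0.8, 0.1)
  labs <- c(1, 1, 1, 1, 0, 0)
  cr3 <- classification_report(probs, labs, threshold = 0.5)
  expect_equal(c(cr3$tp, cr3$tn, cr3$fp, cr3$fn), c(3, 1, 1, 1))
  expect_equal(cr3$accuracy, 4 / 6)
  expect_equal(cr3$balanced_accuracy, (3 / 4 + 1 / 2) / 2)
  expect_warning(classification_report(c(0.4, 0.6), c(1, 1)),
                 "single-class")
})

test_that("exponential-fit baseline extrapolates log-linearly", {
  expect_equal(exp_fit_baseline(0, 1, 1, 2, 2), 4)
  expect_equal(exp_fit_baseline(0, 3, 5, 3, 30), 3)   # flat series
  expect_equal(exp_fit_baseline(2, 1.5, 6, 2.5, 6), 2.5)  # t3 = t2
  expect_error(exp_fit_baseline(0, -1, 1, 2, 2), "PSA levels")
  expect_error(exp_fit_baseline(1, 1, 1, 2, 3), "distinct")
})

test_that("logistic baseline matches the glm oracle", {
  set.seed(33)
  n <- 120
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  eta <- drop(X %*% c(-0.4, 1.1, 0.8))
  y <- rbinom(n, 1, plogis(eta))
  fit <- baseline_logistic_fit(X, y)
  oracle <- glm(y ~ X - 1, family = binomial())
  expect_equal(unname(fit$table$estimate), unname(coef(oracle)),
               tolerance = 1e-8)
  expect_equal(unname(fit$table$std_error),
               unname(summary(oracle)$coefficients[, 2]), tolerance = 1e-5)
  expect_false(fit$separation)
  # duplicated rows: identical coefficients, SEs shrink by sqrt(2)
  fit2 <- baseline_logistic_fit(rbind(X, X), c(y, y))
  expect_equal(fit2$table$estimate, fit$table$estimate, tolerance = 1e-6)
  expect_equal(fit2$table$std_error, fit$table$std_error / sqrt(2),
               tolerance = 1e-6)
  # complete separation is reported, not fatal
  Xs <- cbind(1, c(-2, -1, 1, 2))
  ys <- c(0, 0, 1, 1)
  expect_warning(fs <- baseline_logistic_fit(Xs, ys), "separation")
  expect_true(fs$separation)
  expect_error(baseline_logistic_fit(cbind(1, c(1, 2), c(2, 4)), c(0, 1)),
               "rank deficient")
})

test_that("importance-weighted LOOCV produces sane accuracy summaries", {
  sim <- tiny_cohort(6, seed = 51)
  dr <- sample_posterior(sim$records, prior_config(),
                         quick_cfg(n_iter = 1500, burn_in = 700, thin = 4))
  res <- loocv_predictive(sim$records, draws = dr)
  n_psa <- sum(vapply(sim$records, function(d) length(d$psa_times), 1L))
  n_pet <- sum(vapply(sim$records, function(d) length(d$pet_times), 1L))
  expect_equal(nrow(res$psa), n_psa)
  expect_equal(nrow(res$pet), n_pet)
  expect_true(all(res$psa$pred_density >= 0))
  expect_true(all(res$pet$prob >= 0 & res$pet$prob <= 1))
  expect_true(res$psa_accuracy >= 50 && res$psa_accuracy <= 100)
  if (!is.na(res$pet_balanced_accuracy))
    expect_true(res$pet_balanced_accuracy >= 0 &&
                  res$pet_balanced_accuracy <= 100)
})

test_that("importance-weighted and refit LOOCV agree on a tiny problem", {
  des <- tiny_design(2, seed = 61)
  des$psa_count_range <- c(5, 5); des$pet_count_range <- c(1, 1)
  sim <- simulate_s1(des)
  cfg <- quick_cfg(n_iter = 1600, burn_in = 800, thin = 4, seed = 3)
  imp <- loocv_predictive(sim$records, prior_config(), cfg)
  ref <- loocv_predictive(sim$records, prior_config(), cfg, mode = "refit")
  # same observations evaluated (refit skips nothing here: 4 PSA each)
  expect_equal(nrow(imp$psa), nrow(ref$psa))
  # predictive PET probabilities agree within Monte-Carlo error
  expect_lt(max(abs(imp$pet$prob - ref$pet$prob)), 0.25)
  expect_lt(mean(abs(imp$pet$prob - ref$pet$prob)), 0.12)
})
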