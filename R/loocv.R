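# Leave-one-out cross-validation through the cross-validation predictive
# density. Default mode reuses a single full-data posterior and
# importance-weights each held-out observation (weights proportional to
# the reciprocal of its pointwise likelihood); "refit" mode re-runs the
# sampler without the observation and is exact but expensive.

# weighted empirical quantiles (type-1 style on the weighted CDF)
.wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Leave-one-out predictive evaluation
#'
#' For every observed PSA measurement: the cross-validation predictive
#' density, a 95% predictive interval and whether it contains the held-out
#' value. For every PET-PSMA result: the cross-validation predictive
#' positivity probability and a thresholded classification, the threshold
#' being chosen by ROC analysis of the LOO probabilities (closest point to
#' the (0,1) corner). Aggregates give the PSA predictive accuracy (percent
#' of intervals containing the truth) and the PET accuracy and balanced
#' accuracy.
#'
#' @param data list of [patient_record()] objects.
#' @param priors a [prior_config()].
#' @param cfg an [mcmc_config()]; in refit mode it is used for every
#'   refit, so keep it small.
#' @param mode `"importance"` (default; one full fit, importance-weighted
#'   LOO) or `"refit"` (one fit per held-out observation).
#' @param draws optional pre-computed `psa_draws` for importance mode.
#' @param level predictive-interval level (default 0.95).
#' @return list with `psa` and `pet` per-observation data frames,
#'   `psa_accuracy` (%), `pet_accuracy` (%), `pet_balanced_accuracy` (%)
#'   and the selected `threshold`.
#' @export
loocv_predictive <- function(data, priors = prior_config(),
                             cfg = mcmc_config(), mode = c("importance",
                                                           "refit"),
                             draws = NULL, level = 0.95) {
  mode <- match.arg(mode)
  if (mode == "refit") return(.loocv_refit(data, priors, cfg, level))
  if (is.null(draws)) draws <- sample_posterior(data, priors, cfg)
  pw <- pointwise_loglik(draws, data)
  ll <- pw$ll; obs <- pw$obs
  B <- nrow(ll)
  al <- (1 - level) / 2
  # per-draw patient-level parameters, for predictive draws
  lam <- .pool(draws, "lam"); lmu <- .pool(draws, "lmu")
  lgam <- .pool(draws, "lgam"); la <- .pool(draws, "a")
  tau <- .pool(draws, "tau"); sig2 <- .pool(draws, "sig2")
  abm <- .pool(draws, "alpha_beta")
  b1 <- drop(.pool(draws, "beta1")); b2 <- drop(.pool(draws, "beta2"))
  ids <- draws$ids
  psa_rows <- list(); pet_rows <- list()
  for (k in seq_len(nrow(obs))) {
    # importance weights for holding out observation k:
    # w_b  propto  1 / f(obs_k | theta_b)
    lw <- -ll[, k]
    # a draw with vanishing pointwise likelihood gets the largest finite
    # weight rather than propagating Inf - Inf = NaN
    lw[!is.finite(lw)] <- 700
    lw <- pmin(lw, 700)
    lw <- lw - max(lw)
    w <- exp(lw); w <- w / sum(w)
    j <- match(obs$patient[k], ids)
    t_k <- obs$time[k]
    lx <- .latent_log_psa(lam[, j], exp(lmu[, j]), tau[, j],
                          exp(lgam[, j]), la[, j], t_k)
    if (obs$type[k] == "psa") {
      # predictive density at the held-out value (harmonic-mean identity)
      f_loo <- 1 / sum(w / exp(pmax(ll[, k], -745)))
      ystar <- exp(lx + rnorm(B, 0, sqrt(sig2[, j])))
      qs <- .wquantile(ystar, w, c(al, 1 - al))
      psa_rows[[length(psa_rows) + 1L]] <- data.frame(
        patient = obs$patient[k], time = t_k, value = obs$value[k],
        pred_density = f_loo, lower = qs[1], upper = qs[2],
        covered = obs$value[k] >= qs[1] && obs$value[k] <= qs[2])
    } else {
      d_k <- data[[j]]
      beta0 <- drop(abm %*% d_k$cov_beta)
      pi_b <- positive_prob(lx, t_k, beta0, b1, b2)
      pet_rows[[length(pet_rows) + 1L]] <- data.frame(
        patient = obs$patient[k], time = t_k, value = obs$value[k],
        prob = sum(w * pi_b))
    }
  }
  .loocv_summarise(do.call(rbind, psa_rows), do.call(rbind, pet_rows))
}

.loocv_refit <- function(data, priors, cfg, level) {
  al <- (1 - level) / 2
  psa_rows <- list(); pet_rows <- list()
  for (i in seq_along(data)) {
    d <- data[[i]]
    for (k in seq_along(d$psa_times)) {
      if (length(d$psa_times) <= 1) next  # sampler needs >= 1 PSA point
      held <- list(time = d$psa_times[k], value = d$psa_values[k])
      d2 <- d
      d2$psa_times <- d$psa_times[-k]; d2$psa_values <- d$psa_values[-k]
      dat2 <- data; dat2[[i]] <- d2
      dr <- sample_posterior(dat2, priors, cfg)
      j <- .patient_index(dr, d$patient_id)
      lam <- .pool(dr, "lam")[, j]; lmu <- .pool(dr, "lmu")[, j]
      lgam <- .pool(dr, "lgam")[, j]; la <- .pool(dr, "a")[, j]
      tau <- .pool(dr, "tau")[, j]; sig2 <- .pool(dr, "sig2")[, j]
      lx <- .latent_log_psa(lam, exp(lmu), tau, exp(lgam), la,
                            held$time)
      ystar <- exp(lx + rnorm(length(lx), 0, sqrt(sig2)))
      qs <- quantile(ystar, c(al, 1 - al))
      f_loo <- mean(dlnorm(held$value, lx, sqrt(sig2)))
      psa_rows[[length(psa_rows) + 1L]] <- data.frame(
        patient = as.character(d$patient_id), time = held$time,
        value = held$value, pred_density = f_loo,
        lower = qs[1], upper = qs[2],
        covered = held$value >= qs[1] && held$value <= qs[2])
    }
    for (k in seq_along(d$pet_times)) {
      held <- list(time = d$pet_times[k], value = d$pet_results[k])
      d2 <- d
      d2$pet_times <- d$pet_times[-k]; d2$pet_results <- d$pet_results[-k]
      dat2 <- data; dat2[[i]] <- d2
      dr <- sample_posterior(dat2, priors, cfg)
      j <- .patient_index(dr, d$patient_id)
      lam <- .pool(dr, "lam")[, j]; lmu <- .pool(dr, "lmu")[, j]
      lgam <- .pool(dr, "lgam")[, j]; la <- .pool(dr, "a")[, j]
      tau <- .pool(dr, "tau")[, j]
      abm <- .pool(dr, "alpha_beta")
      b1 <- drop(.pool(dr, "beta1")); b2 <- drop(.pool(dr, "beta2"))
      lx <- .latent_log_psa(lam, exp(lmu), tau, exp(lgam), la,
                            held$time)
      pi_b <- positive_prob(lx, held$time, drop(abm %*% d$cov_beta),
                            b1, b2)
      pet_rows[[length(pet_rows) + 1L]] <- data.frame(
        patient = as.character(d$patient_id), time = held$time,
        value = held$value, prob = mean(pi_b))
    }
  }
  .loocv_summarise(do.call(rbind, psa_rows), do.call(rbind, pet_rows))
}

.loocv_summarise <- function(psa, pet) {
  psa_acc <- if (!is.null(psa) && nrow(psa)) 100 * mean(psa$covered)
             else NA_real_
  threshold <- NA_real_; pet_acc <- NA_real_; pet_bal <- NA_real_
  if (!is.null(pet) && nrow(pet) && length(unique(pet$value)) == 2) {
    roc <- roc_auc(pet$prob, pet$value)
    threshold <- roc$best_threshold
    cr <- classification_report(pet$prob, pet$value, threshold)
    pet_acc <- 100 * cr$accuracy
    pet_bal <- 100 * cr$balanced_accuracy
  }
  list(psa = psa, pet = pet, psa_accuracy = psa_acc,
       pet_accuracy = pet_acc, pet_balanced_accuracy = pet_bal,
       threshold = threshold)
}
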