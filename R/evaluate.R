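# Diagnostics and validation: convergence, coverage, WAIC, ROC/AUC,
# classification metrics and the two simple clinical baselines.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic R-hat from between- and within-chain variances. A single chain
#' is split in half. Zero-variance chains return exactly 1.
#'
#' @param chains a matrix (iterations x chains), a list of equal-length
#'   numeric vectors, or a single numeric vector (split in half).
#' @return scalar R-hat (>= 1 up to numerical noise).
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  if (is.null(dim(chains))) {
    m <- length(chains) %/% 2
    chains <- cbind(chains[seq_len(m)], chains[m + seq_len(m)])
  }
  n <- nrow(chains); m <- ncol(chains)
  if (n < 4) stop("chains must have length >= 4")
  W <- mean(apply(chains, 2, var))
  if (W == 0 || !is.finite(W)) return(1)
  B <- n * var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# R-hat for each column of a parameter family inside a psa_draws object,
# splitting each chain in half so a single chain still yields a diagnostic
.rhat_family <- function(draws, name) {
  ncol_par <- ncol(draws$chains[[1]][[name]])
  vapply(seq_len(ncol_par), function(j) {
    halves <- unlist(lapply(draws$chains, function(ch) {
      x <- ch[[name]][, j]
      m <- length(x) %/% 2
      list(x[seq_len(m)], x[m + seq_len(m)])
    }), recursive = FALSE)
    rhat(halves)
  }, numeric(1))
}

#' Credible-interval coverage of patient-level parameters
#'
#' For each parameter family (`lam`, `tau`, `log_mu`, `log_gamma`,
#' `a`, `sigma2`) computes per-patient equal-tailed 95% credible
#' intervals from the pooled draws, the percentage of patients whose
#' interval contains the generating value, the 2.5%/mean/97.5% summary of
#' the interval widths, and the same summary of per-patient R-hat.
#' Equal-tailed quantile intervals make the coverage of `mu`, `gamma`
#' and `a` identical on the log and natural scales.
#'
#' @param draws a `psa_draws` object.
#' @param truth list of generating [trajectory_params()], one per patient,
#'   in the same order as the fitted data.
#' @param level credible level (default 0.95).
#' @return data frame of class `coverage_report` with one row per family.
#' @export
coverage_table <- function(draws, truth, level = 0.95) {
  n <- draws$n_patients
  if (length(truth) != n) stop("draws/truth patient mismatch")
  al <- (1 - level) / 2
  fam <- list(
    lam = list(draw = "lam", get = function(p) p$lam),
    tau = list(draw = "tau", get = function(p) p$tau),
    log_mu = list(draw = "lmu", get = function(p) log(p$mu)),
    log_gamma = list(draw = "lgam", get = function(p) log(p$gamma)),
    a = list(draw = "a", get = function(p) p$a),
    sigma2 = list(draw = "sig2", get = function(p) p$sigma2))
  rows <- lapply(names(fam), function(nm) {
    f <- fam[[nm]]
    mat <- .pool(draws, f$draw)
    tv <- vapply(truth, f$get, numeric(1))
    lo <- apply(mat, 2, quantile, probs = al)
    hi <- apply(mat, 2, quantile, probs = 1 - al)
    rh <- .rhat_family(draws, f$draw)
    w <- hi - lo
    data.frame(parameter = nm,
               coverage_pct = 100 * mean(tv >= lo & tv <= hi),
               ciw_q025 = quantile(w, 0.025), ciw_mean = mean(w),
               ciw_q975 = quantile(w, 0.975),
               rhat_q025 = quantile(rh, 0.025), rhat_mean = mean(rh),
               rhat_q975 = quantile(rh, 0.975),
               row.names = NULL)
  })
  structure(do.call(rbind, rows),
            class = c("coverage_report", "data.frame"))
}

#' Watanabe-Akaike information criterion
#'
#' `lppd = sum_j log mean_b exp(ll[b, j])`, `p_waic = sum_j var_b ll[b, j]`,
#' `waic = -2 (lppd - p_waic)`.
#'
#' @param ll matrix of pointwise log-likelihoods (draws x observations),
#'   e.g. the `ll` element of [pointwise_loglik()].
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(ll) {
  if (!is.matrix(ll) || nrow(ll) < 2)
    stop("ll must be a matrix with >= 2 draws")
  if (any(!is.finite(ll) & ll > -Inf))
    stop("non-finite log-likelihood values")
  # column-wise log-mean-exp, stable
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the unique score values in decreasing order as thresholds,
#' returning the ROC points, the trapezoid AUC, and the operating
#' threshold closest to the ideal corner (0, 1).
#'
#' @param scores predicted probabilities (or any monotone scores).
#' @param labels binary outcomes.
#' @return list with `roc` (data frame: threshold, fpr, tpr), `auc`, and
#'   `best_threshold`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("both label classes must be present")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / P, 1)
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / N, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  d <- sqrt(fpr^2 + (1 - tpr)^2)
  best <- th[which.min(d)]
  list(roc = data.frame(threshold = th, fpr = fpr, tpr = tpr),
       auc = auc, best_threshold = best)
}

#' Confusion-matrix classification metrics
#'
#' @param predicted_probs predicted positive probabilities.
#' @param labels binary outcomes.
#' @param threshold classification threshold (predict 1 when the
#'   probability is >= threshold).
#' @return list with `accuracy`, `balanced_accuracy`, `sensitivity`,
#'   `specificity` and the confusion counts `tp`, `tn`, `fp`, `fn`.
#' @export
classification_report <- function(predicted_probs, labels, threshold = 0.5) {
  stopifnot(all(labels %in% c(0, 1)))
  pred <- as.integer(predicted_probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (length(unique(labels)) < 2)
    warning("single-class labels: balanced accuracy undefined")
  list(accuracy = (tp + tn) / length(labels),
       balanced_accuracy = mean(c(sens, spec)),
       sensitivity = sens, specificity = spec,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Exponential-fit PSA baseline
#'
#' The simple clinical baseline: fit exponential growth through two PSA
#' measurements and extrapolate,
#' `psa(t3) = psa2 * (psa2 / psa1)^((t3 - t2) / (t2 - t1))`.
#'
#' @param t1,psa1 first measurement time and level.
#' @param t2,psa2 second measurement time and level (`t2 > t1`).
#' @param t3 prediction time (`t3 >= t2`).
#' @return predicted PSA level at `t3`.
#' @export
exp_fit_baseline <- function(t1, psa1, t2, psa2, t3) {
  if (any(psa1 <= 0) || any(psa2 <= 0)) stop("PSA levels must be > 0")
  if (any(t2 <= t1)) stop("times must be distinct and increasing")
  psa2 * (psa2 / psa1)^((t3 - t2) / (t2 - t1))
}

#' Maximum-likelihood logistic regression baseline
#'
#' Fits the simple logistic model (baseline covariates + observed log-PSA
#' + time) by iteratively reweighted least squares, with Wald standard
#' errors and p-values. Complete separation is reported via a warning, not
#' an error.
#'
#' @param X design matrix (including the intercept column).
#' @param y binary response.
#' @param max_iter,tol IRLS controls.
#' @return list with `table` (data frame: estimate, std_error, p_value),
#'   `converged`, `separation` flag, and the fitted probabilities `fitted`.
#' @export
baseline_logistic_fit <- function(X, y, max_iter = 50, tol = 1e-10) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    zwork <- eta + (y - p) / w
    fit <- lm.wfit(X, zwork, w)
    step <- fit$coefficients - beta
    beta <- fit$coefficients
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  separation <- !converged || max(abs(beta)) > 1e2
  if (separation)
    warning("possible separation: coefficients diverging or IRLS not ",
            "converged")
  p <- plogis(drop(X %*% beta))
  W <- p * (1 - p)
  info <- crossprod(X, X * W)
  se <- sqrt(diag(solve(info)))
  zstat <- beta / se
  tab <- data.frame(estimate = beta, std_error = se,
                    p_value = 2 * pnorm(-abs(zstat)),
                    row.names = colnames(X))
  list(table = tab, converged = converged, separation = separation,
       fitted = p)
}
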