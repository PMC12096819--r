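# Decision layer: posterior-predictive probability curves and the optimal
# PET-PSMA time.

#' Per-draw predictive positivity curves
#'
#' For every kept posterior draw `b` and every grid time `t`, evaluates the
#' latent log-PSA trajectory with the draw's patient-level parameters and
#' maps it through the logistic link with the draw's coefficients, giving
#' the matrix of predictive positivity probabilities `pi[b, t]`; the
#' draw's change point is passed through alongside.
#'
#' @param draws a `psa_draws` object from [sample_posterior()].
#' @param patient the [patient_record()] of the patient of interest (must
#'   have been part of the fit).
#' @param grid evaluation times (months, >= 0).
#' @return list with `pi` (draws x grid matrix), `tau` (vector of
#'   change-point draws), `log_x` (draws x grid latent levels) and `grid`.
#' @export
predictive_curves <- function(draws, patient, grid) {
  if (any(grid < 0)) stop("grid times must be >= 0")
  j <- .patient_index(draws, patient$patient_id)
  lam <- .pool(draws, "lam")[, j]
  mu <- exp(.pool(draws, "lmu")[, j])
  gam <- exp(.pool(draws, "lgam")[, j])
  a <- .pool(draws, "a")[, j]
  tau <- .pool(draws, "tau")[, j]
  sig2 <- .pool(draws, "sig2")[, j]
  beta0 <- drop(.pool(draws, "alpha_beta") %*% patient$cov_beta)
  b1 <- drop(.pool(draws, "beta1")); b2 <- drop(.pool(draws, "beta2"))
  B <- length(lam); G <- length(grid)
  # draws x grid evaluation: expand over the grid per draw (vectorised
  # over the long draws dimension)
  tg <- rep(grid, each = B)
  lx <- .latent_log_psa(rep(lam, G), rep(mu, G), rep(tau, G),
                        rep(gam, G), rep(a, G), tg)
  pi <- positive_prob(lx, tg, rep(beta0, G), rep(b1, G), rep(b2, G))
  list(pi = matrix(pi, B, G), tau = tau,
       log_x = matrix(lx, B, G), grid = grid, sigma2 = sig2)
}

#' Monte-Carlo satisfaction probability at one time
#'
#' The proportion of posterior draws in the event \{positivity probability
#' at `t` at least `pi_star` and change point before `t`\}:
#' `mean(pi_t >= pi_star & tau < t)`. Ties on the probability scale are
#' counted towards recommending the exam.
#'
#' @param pi_t vector of per-draw positivity probabilities at time `t`.
#' @param tau vector of per-draw change points.
#' @param pi_star target positivity probability.
#' @param t the evaluation time.
#' @return scalar probability in `[0, 1]`.
#' @export
satisfaction_probability <- function(pi_t, tau, pi_star, t) {
  if (!length(pi_t)) stop("empty draw set")
  stopifnot(length(pi_t) == length(tau))
  mean(pi_t >= pi_star & tau < t)
}

#' Optimal time to recommend a PET-PSMA examination
#'
#' Evaluates the satisfaction probability over a time grid and returns the
#' smallest grid time at or past the patient's last observation whose
#' probability reaches the assurance level `rho`. When no grid time
#' qualifies the result is explicitly "not reached" (`t_star = NA`).
#'
#' @param draws a `psa_draws` object.
#' @param patient the [patient_record()] of interest.
#' @param design a [design_params()] object; if its `time_grid` is `NULL`,
#'   a 1-month grid from 0 to 60 months past the last observation is used.
#' @return an object of class `optimal_time_result` with fields
#'   `patient_id`, `time_grid`, `prob_satisfied`, `t_star` (NA if not
#'   reached), `reached`, `pi_star`, `rho`.
#' @export
optimal_time <- function(draws, patient, design) {
  stopifnot(inherits(design, "design_params"))
  t_max <- max(c(patient$psa_times, patient$pet_times))
  grid <- design$time_grid
  if (is.null(grid)) grid <- seq(0, ceiling(t_max) + 60, by = 1)
  if (max(grid) < t_max)
    stop("time grid ends before the patient's last observation")
  cv <- predictive_curves(draws, patient, grid)
  prob <- vapply(seq_along(grid), function(g)
    satisfaction_probability(cv$pi[, g], cv$tau, design$pi_star, grid[g]),
    numeric(1))
  eligible <- grid >= t_max
  hit <- which(eligible & prob >= design$rho)
  structure(list(patient_id = patient$patient_id, time_grid = grid,
                 prob_satisfied = prob,
                 t_star = if (length(hit)) grid[hit[1]] else NA_real_,
                 reached = length(hit) > 0,
                 pi_star = design$pi_star, rho = design$rho),
            class = "optimal_time_result")
}

#' @export
print.optimal_time_result <- function(x, ...) {
  cat("<optimal_time_result> patient", format(x$patient_id),
      sprintf("(pi* = %.2f, rho = %.2f): ", x$pi_star, x$rho))
  if (x$reached) cat("recommend PET-PSMA at t* =", x$t_star, "months\n")
  else cat("assurance level not reached on the grid\n")
  invisible(x)
}

#' Optimal-time table for a whole cohort
#'
#' @param draws a `psa_draws` object.
#' @param data list of [patient_record()] objects.
#' @param design a [design_params()] object.
#' @return data frame with one row per patient: `patient_id`, `t_star`,
#'   `reached`, and the probability at `t_star` (NA when not reached).
#' @export
optimal_time_table <- function(draws, data, design) {
  rows <- lapply(data, function(d) {
    r <- optimal_time(draws, d, design)
    p <- if (r$reached) r$prob_satisfied[match(r$t_star, r$time_grid)]
         else NA_real_
    data.frame(patient_id = as.character(d$patient_id),
               t_star = r$t_star, reached = r$reached,
               prob_at_t_star = p)
  })
  do.call(rbind, rows)
}
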