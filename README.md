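# psajoint

Joint Bayesian modelling of post-prostatectomy PSA kinetics and PET-PSMA
positivity, with a posterior-predictive estimator of the optimal time to
recommend the exam.

## The problem

After radical prostatectomy, patients are monitored through serum PSA
(prostate-specific antigen, ng/mL). A PSA resurgence signals biochemical
recurrence; the PET-PSMA examination can locate the recurrent tumour but
is expensive and, performed too early, likely falsely negative. The
decision this package supports: *given everything measured so far, when
should this patient's PET-PSMA be scheduled?*

## The model

Each patient's latent log-PSA declines linearly until a patient-specific
change point τ (resurgence onset), then follows a log-Gompertz curve
towards an asymptote *a*:

    log x(t) = λ − μ t                                   t ≤ τ
    log x(t) = log x(τ) e(t) + a (1 − e(t)),  e(t) = exp(−γ (t − τ))

Observed log-PSA is Gaussian around log x(t) with variance σ²; a PET-PSMA
at time t is positive with probability
logit π(t) = β₀ + β₁ log x(t) + β₂ t. Random effects with covariate-
dependent means tie the patients together (log μ, log γ Gaussian given
covariates; a Gaussian; σ² inverse-gamma). Inference is adaptive
Metropolis-within-Gibbs MCMC with Pólya-Gamma augmentation of the
logistic block (exact Devroye sampler in C++). The optimal exam time t\*
is the first time at or after the last observation where

    P( π(t) > π*  and  τ < t | data ) ≥ ρ

estimated by the Monte-Carlo proportion of posterior draws satisfying
both conditions (π\* is the target positivity probability, ρ the
posterior assurance, default 0.95).

No clinical data ship with the package; synthetic-cohort generators
(`simulate_s1()`, `simulate_scenarios()`, `simulate_cohort()`) reproduce
the published simulation designs so every layer is testable. See the
methods vignette (`vignettes/psajoint-methods.Rmd`) for the full model,
prior, sampler and design discussion.

## Worked example

```r
library(psajoint)

# a synthetic stress-test cohort with known generating parameters
sim <- simulate_s1(sim_design(seed = 42))

# fit (reduced length; published analyses used 150k/100k/10)
draws <- sample_posterior(sim$records, prior_config(),
                          mcmc_config(n_iter = 20000, burn_in = 10000,
                                      thin = 10, seed = 1))
print(draws)
#> <psa_draws> 1 chain(s) x 1000 kept draws, 80 patients
#> mean acceptance rates:
#>    patient      joint        tau       w_mu    w_gamma sig2_hyper
#>      0.439      0.233      0.229      0.440      0.439      0.438

# how often do the 95% credible intervals cover the generating values?
coverage_table(draws, sim$truth_traj)
#>   parameter coverage_pct ciw_q025 ciw_mean ciw_q975 rhat_q025 rhat_mean rhat_q975
#> 1       lam         93.8   4.1430    7.515   14.459     0.999      1.00      1.01
#> 2       tau         95.0   0.1920    1.169    3.232     0.999      1.00      1.01
#> 3    log_mu         97.5   0.0698    0.205    0.325     0.999      1.00      1.01
#> 4 log_gamma         93.8   0.1401    0.326    0.426     0.999      1.00      1.02
#> 5         a         96.2   1.9204    2.568    3.541     0.999      1.01      1.02
#> 6    sigma2         98.8   3.5096    6.778   16.859     0.999      1.00      1.01
```

Coverage sits at the nominal 95% for every parameter family (the
published stress test reports 91–100%), interval widths are finite and
split-half R-hat is at 1: the sampler recovers the generating
parameters. For one patient, the decision layer:

```r
res <- optimal_time(draws, sim$records[[3]],
                    design_params(pi_star = 0.63, rho = 0.95))
print(res)
#> <optimal_time_result> patient P003 (pi* = 0.63, rho = 0.95):
#>   recommend PET-PSMA at t* = 48 months
```

Patient P003's last observation is at 34 months; the first grid time at
which at least 95% of posterior draws have positivity probability above
0.63 *and* the change point already passed is 48 months.

`res$prob_satisfied` holds the whole probability curve over the grid;
`optimal_time_table()` does the same for a cohort, and `psa_cli()`
exposes `simulate`, `fit`, `optimal-time`, `evaluate` and `loocv`
subcommands for file-based pipelines (long CSV in, CSV reports out).

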