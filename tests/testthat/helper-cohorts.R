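# Simulate a cohort of agents sharing one omega (or a vector of omegas),
# returning bound trial records. Used by behavioural-signature tests.
simulate_cohort_trials <- function(omegas, n_trials = 300L, beta = 2,
                                   lam = 1, alpha = 0.6, rep = 0.2,
                                   p_common = 0.7) {
  cfg <- task_config(n_trials = n_trials, p_common = p_common)
  purrr::map(seq_along(omegas), function(i) {
    simulate_agent(
      hybrid_params(alpha1 = alpha, alpha2 = alpha, lam = lam,
                    beta1 = beta, beta2 = beta, omega = omegas[i],
                    rep = rep),
      cfg, subject = sprintf("c%03d", i)
    )
  }) |> dplyr::bind_rows()
}

# EMA generator configuration with the hurdle switched off (every day is a
# drinking day) and a chosen omega-by-'less' interaction on the log-gram
# scale; used for coverage / type-I / ICC experiments where the analysis
# model and the generator must coincide.
gaussian_ema_config <- function(interaction = -1, slope_sd = 0.3,
                                intercept_sd = 0.8, residual_sd = 0.8,
                                ...) {
  ema_config(
    drink_coef = c(intercept = 20),
    amount_coef = c(intercept = 3.5, no_more = 0.29, less = 0.14,
                    omega = -0.17, omega_no_more = -0.49,
                    omega_less = interaction),
    amount_intercept_sd = intercept_sd,
    amount_slope_sd = slope_sd,
    residual_sd = residual_sd,
    ...
  )
}

simulate_daily <- function(cfg) {
  co <- simulate_ema_cohort(cfg)
  list(daily = restructure_ema(co$ratings, co$reports), traits = co$traits)
}
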