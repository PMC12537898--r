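make_small_fit <- function(seed = 71, n_subjects = 25, horizon = 120,
                           dependent = "log_grams", ...) {
  set.seed(seed)
  sim <- simulate_daily(gaussian_ema_config(n_subjects = n_subjects,
                                            horizon = horizon, ...))
  fit <- suppressWarnings(
    fit_moderation(sim$daily, sim$traits, dependent = dependent)
  )
  list(fit = fit, sim = sim)
}

test_that("dummy coding uses 'no specific intention' as reference", {
  daily <- tibble::tibble(
    subject = rep("a", 3), day = 1:3, grams = c(0, 10, 5),
    intention = c("none", "less", "no_more"), valid = TRUE
  )
  traits <- tibble::tibble(subject = "a", omega = 0.5)
  data <- build_moderation_data(daily, traits)
  expect_equal(data$int_less, c(0, 1, 0))
  expect_equal(data$int_no_more, c(0, 0, 1))
  expect_equal(data$log_grams, log1p(c(0, 10, 5)))
  expect_equal(data$drink, c(0L, 1L, 1L))
})

test_that("the moderation LMM recovers its coefficient table contracts", {
  res <- make_small_fit()
  fit <- res$fit
  expect_s3_class(fit, "moderation_fit")
  cf <- tidy(fit)
  expect_setequal(
    cf$term,
    c("(Intercept)", "int_no_more", "int_less", "omega",
      "int_no_more:omega", "int_less:omega")
  )
  expect_true(all(cf$conf_low <= cf$estimate & cf$estimate <= cf$conf_high))
  expect_true(all(fit$varcomp$variance >= 0))
  expect_equal(unique(cf$df), fit$n_obs - nrow(cf))
  gl <- glance(fit)
  expect_equal(gl$dependent, "log_grams")
})

test_that("profile confidence intervals are available for the LMM", {
  res <- make_small_fit(seed = 72, n_subjects = 15, horizon = 60)
  set.seed(72)
  sim <- res$sim
  fit_p <- suppressWarnings(
    fit_moderation(sim$daily, sim$traits, ci_method = "profile")
  )
  cf <- tidy(fit_p)
  expect_true(all(cf$conf_low < cf$estimate & cf$estimate < cf$conf_high))
  # profile and Wald agree to first order at this sample size
  cw <- tidy(res$fit)
  expect_equal(cf$estimate, cw$estimate, tolerance = 1e-6)
})

test_that("marginal means equal the plug-in arithmetic", {
  res <- make_small_fit(seed = 73)
  fit <- res$fit
  mm <- marginal_means(fit, at = list(omega = c(0.3, 0.7)))
  cf <- fit$coefficients
  b <- setNames(cf$estimate, cf$term)
  for (i in seq_len(nrow(mm))) {
    x_less <- as.numeric(mm$intention[i] == "less")
    x_nomore <- as.numeric(mm$intention[i] == "no_more")
    eta <- b["(Intercept)"] + b["int_no_more"] * x_nomore +
      b["int_less"] * x_less + b["omega"] * mm$omega[i] +
      b["int_no_more:omega"] * x_nomore * mm$omega[i] +
      b["int_less:omega"] * x_less * mm$omega[i]
    expect_equal(mm$response[i], expm1(unname(eta)), tolerance = 1e-8)
  }
  expect_warning(marginal_means(fit, at = list(omega = 3)), "outside")
  expect_error(marginal_means(fit, at = list(nope = 1)), "unknown trait")
})

test_that("marginal means match emmeans on the same model", {
  skip_if_not_installed("emmeans")
  res <- make_small_fit(seed = 74)
  fit <- res$fit
  mm <- marginal_means(fit, at = list(omega = 0.5))
  em <- as.data.frame(emmeans::emmeans(
    fit$model, ~ int_less * int_no_more * omega,
    at = list(int_less = c(0, 1), int_no_more = c(0, 1), omega = 0.5),
    lmer.df = "asymptotic"
  ))
  # match rows: none = (0,0), less = (1,0), no_more = (0,1)
  pick <- function(l, nm) em$emmean[em$int_less == l & em$int_no_more == nm]
  expect_equal(mm$link[mm$intention == "none"], pick(0, 0), tolerance = 1e-6)
  expect_equal(mm$link[mm$intention == "less"], pick(1, 0), tolerance = 1e-6)
  expect_equal(mm$link[mm$intention == "no_more"], pick(0, 1),
               tolerance = 1e-6)
})

test_that("logistic marginal means are probabilities", {
  set.seed(75)
  cfg <- ema_config(n_subjects = 25, horizon = 120,
                    drink_coef = c(intercept = 0.7, omega_less = -1.2),
                    amount_coef = c(intercept = 3.5))
  sim <- simulate_daily(cfg)
  fit <- suppressWarnings(
    fit_moderation(sim$daily, sim$traits, dependent = "drink_indicator")
  )
  mm <- marginal_means(fit, at = list(omega = c(0.3, 0.7)))
  expect_true(all(mm$response >= 0 & mm$response <= 1))
  expect_true(all(mm$conf_low <= mm$response))
})

test_that("random-structure selection favours real slope variance", {
  set.seed(76)
  sim <- simulate_daily(gaussian_ema_config(slope_sd = 0.6))
  sel <- select_random_structure(sim$daily, sim$traits)
  expect_equal(sel$structure, "slopes_uncorrelated")
  expect_lt(sel$lrt$p[sel$lrt$comparison ==
                        "slopes_uncorrelated vs intercept"], 0.05)

  set.seed(77)
  sim0 <- simulate_daily(gaussian_ema_config(slope_sd = 0,
                                             n_subjects = 30,
                                             horizon = 120))
  sel0 <- select_random_structure(sim0$daily, sim0$traits)
  expect_equal(sel0$structure, "intercept")
})

test_that("single-category data make slope structures unidentifiable", {
  set.seed(78)
  cfg <- gaussian_ema_config(n_subjects = 12, horizon = 48,
                             intention_stationary = c(none = 1, no_more = 0,
                                                      less = 0))
  sim <- simulate_daily(cfg)
  sel <- suppressWarnings(select_random_structure(sim$daily, sim$traits))
  # no intention contrast ever varies, so slopes cannot improve the fit
  expect_equal(sel$structure, "intercept")
})

test_that("ICC arithmetic and degenerate cases behave", {
  # within-share is the complement
  set.seed(79)
  sim <- simulate_daily(gaussian_ema_config(n_subjects = 20, horizon = 80))
  res <- icc_unconditional(sim$daily)
  expect_equal(res$within_share, 1 - res$icc)
  expect_gt(res$icc, 0)

  const <- tibble::tibble(subject = rep(c("a", "b"), each = 5),
                          day = rep(1:5, 2), grams = 7,
                          intention = "none", valid = TRUE)
  expect_message(res0 <- icc_unconditional(const), "undefined")
  expect_true(is.na(res0$icc))
})

test_that("drinking is dichotomized exactly at zero grams", {
  daily <- tibble::tibble(
    subject = rep(c("a", "b"), each = 4), day = rep(1:4, 2),
    grams = c(0, 0.5, 80, 0, 12, 0, 3, 0),
    intention = rep(c("none", "less", "no_more", "none"), 2), valid = TRUE
  )
  traits <- tibble::tibble(subject = c("a", "b"), omega = c(0.2, 0.8))
  data <- build_moderation_data(daily, traits)
  expect_equal(data$drink, as.integer(daily$grams > 0))
})

test_that("an all-drinking cohort raises the separation flag", {
  set.seed(80)
  sim <- simulate_daily(gaussian_ema_config(n_subjects = 12, horizon = 48))
  sim$daily$grams <- sim$daily$grams + 1 # no abstinent day left
  expect_warning(
    fit <- fit_glmm_drinking(sim$daily, sim$traits),
    "separated"
  )
  expect_true(fit$separation_flag)
})

test_that("the drinking GLMM recovers a negative omega-by-less interaction", {
  set.seed(81)
  cfg <- ema_config(
    drink_coef = c(intercept = 1.2, omega_less = -2.5),
    amount_coef = c(intercept = 3.5),
    missingness = 0.1
  )
  sim <- simulate_daily(cfg)
  fit <- suppressWarnings(fit_glmm_drinking(sim$daily, sim$traits))
  row <- fit$coefficients[fit$coefficients$term == "int_less:omega", ]
  expect_lt(row$estimate, 0)
  expect_true("odds_ratio" %in% names(fit$coefficients))
  expect_equal(row$odds_ratio, exp(row$estimate))
})

test_that("an irrelevant covariate barely moves the moderation estimate", {
  change <- purrr::map_dbl(1:2, function(k) {
    set.seed(82 + k)
    sim <- simulate_daily(gaussian_ema_config())
    sim$traits$noise_cov <- rnorm(nrow(sim$traits))
    f1 <- suppressWarnings(fit_moderation(sim$daily, sim$traits))
    f2 <- suppressWarnings(
      fit_moderation(sim$daily, sim$traits,
                     traits_terms = c("omega", "noise_cov"))
    )
    e1 <- f1$coefficients$estimate[f1$coefficients$term == "int_less:omega"]
    e2 <- f2$coefficients$estimate[f2$coefficients$term == "int_less:omega"]
    abs(e2 - e1) / abs(e1)
  })
  expect_lt(mean(change), 0.10)
})

test_that("LMM and GLMM agree in interaction sign on coupled generators", {
  set.seed(85)
  cfg <- ema_config(
    drink_coef = c(intercept = 1.5, omega_less = -1.8),
    amount_coef = c(intercept = 3.5, omega_less = -1.2),
    missingness = 0.1
  )
  sim <- simulate_daily(cfg)
  lmm <- suppressWarnings(fit_moderation(sim$daily, sim$traits))
  glmm <- suppressWarnings(fit_glmm_drinking(sim$daily, sim$traits))
  pick <- function(f) {
    f$coefficients$estimate[f$coefficients$term == "int_less:omega"]
  }
  expect_lt(pick(lmm), 0)
  expect_lt(pick(glmm), 0)
})

test_that("diagnostics report residuals and subject leverage", {
  res <- make_small_fit(seed = 86, n_subjects = 12, horizon = 48)
  di <- moderation_diagnostics(res$fit)
  expect_equal(nrow(di$subjects), 12)
  expect_equal(nrow(di$residuals), res$fit$n_obs)
})
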