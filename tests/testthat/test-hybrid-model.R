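test_that("hybrid_params enforces bounds", {
  expect_error(hybrid_params(alpha1 = 1.2), "alpha1")
  expect_error(hybrid_params(beta1 = -1), "beta1")
  expect_error(hybrid_params(omega = NA), "finite")
  p <- hybrid_params(omega = 0.3)
  expect_s3_class(p, "hybrid_params")
})

test_that("parameters round-trip through JSON with bounds checked", {
  p <- hybrid_params(alpha1 = 0.3, beta1 = 2.5, omega = 0.9, rep = -0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_hybrid_params(p, path)
  expect_equal(read_hybrid_params(path), p)
  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$omega <- 1.4
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_hybrid_params(path2), "omega")
  jsonlite::write_json(bad[-1], path2, auto_unbox = TRUE)
  expect_error(read_hybrid_params(path2), "missing field")
})

test_that("model-based values weight the best second-stage option", {
  # direct arithmetic oracle
  q2 <- matrix(c(1, 3, 2, 4), 2) # state0: (1,2); state1: (3,4)
  expect_equal(mb_values(q2, 0.7), c(0.7 * 2 + 0.3 * 4, 0.7 * 4 + 0.3 * 2))
  # symmetry and uninformative-transition cases
  expect_equal(mb_values(matrix(7, 2, 2), 0.9), c(7, 7))
  v <- mb_values(q2, 0.5)
  expect_equal(v[1], v[2])
})

test_that("choice probabilities are a softmax with perseveration", {
  expect_equal(choice_probabilities(c(2, 2), 3), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(-1, 5), 0), c(0.5, 0.5))
  p <- choice_probabilities(c(2.6, 3.4), 1)
  expect_equal(p, c(1, exp(0.8)) / (1 + exp(0.8)), tolerance = 1e-12)
  # perseveration shifts toward the previous action
  p_rep <- choice_probabilities(c(2.6, 3.4), 1, prev_a1 = 0L, rep = 2)
  expect_gt(p_rep[1], p[1])
  # overflow-safe for extreme temperatures
  p_hot <- choice_probabilities(c(0, 1), 1e6)
  expect_equal(p_hot[2], 1)
  expect_false(any(is.nan(p_hot)))
})

test_that("value updates follow the SARSA(lambda) hand computation", {
  latent <- mbema:::new_latent_values()
  latent <- mbema:::latent_with_mb(latent, hybrid_params(), 0.7)

  frozen <- update_values(latent, list(a1 = 0L, s2 = 0L, a2 = 1L, points = 4),
                          hybrid_params(alpha1 = 0.5, alpha2 = 0.5, lam = 1))
  expect_equal(frozen$delta1, 0)
  expect_equal(frozen$delta2, 4)
  expect_equal(frozen$q2[1, 2], 2)
  expect_equal(frozen$q_mf1[1], 2)

  # no learning at zero rates
  still <- update_values(latent, list(a1 = 1L, s2 = 0L, a2 = 0L, points = -3),
                         hybrid_params(alpha1 = 0, alpha2 = 0, lam = 1))
  expect_equal(still$q_mf1, latent$q_mf1)
  expect_equal(still$q2, latent$q2)

  # with the trace off, the outcome error does not reach stage 1
  l2 <- latent
  l2$q2[1, 2] <- 1 # nonzero so delta1 != 0
  l2 <- mbema:::latent_with_mb(l2, hybrid_params(), 0.7)
  no_trace <- update_values(l2, list(a1 = 0L, s2 = 0L, a2 = 1L, points = 4),
                            hybrid_params(alpha1 = 0.5, alpha2 = 0.5,
                                          lam = 0))
  expect_equal(no_trace$q_mf1[1], 0 + 0.5 * (1 - 0)) # alpha1 * delta1 only
})

test_that("net first-stage values mix model-based and model-free exactly", {
  set.seed(8)
  for (k in 1:20) {
    params <- hybrid_params(alpha1 = runif(1), alpha2 = runif(1),
                            lam = runif(1), omega = runif(1))
    latent <- mbema:::new_latent_values()
    latent$q_mf1 <- rnorm(2)
    latent$q2 <- matrix(rnorm(4), 2)
    latent <- mbema:::latent_with_mb(latent, params, 0.7)
    expect_equal(
      max(abs(latent$q_net1 -
                (params$omega * latent$q_mb1 +
                   (1 - params$omega) * latent$q_mf1))), 0)
  }
})

test_that("simulated agents show the canonical behavioural signatures", {
  set.seed(21)
  # pure model-based: stay more after rewarded-common than rewarded-rare
  mb <- simulate_cohort_trials(rep(1, 10), n_trials = 500, beta = 3, rep = 0)
  rows <- build_stay_table(mb)
  stay_rc <- with(rows, mean(stay[prev_outcome == "reward" &
                                    prev_transition == "common"]))
  stay_rr <- with(rows, mean(stay[prev_outcome == "reward" &
                                    prev_transition == "rare"]))
  expect_gt(stay_rc, stay_rr)

  # pure model-free with full trace: reward raises staying in both
  # transition types
  set.seed(22)
  mf <- simulate_cohort_trials(rep(0, 10), n_trials = 500, beta = 3, rep = 0)
  rows_mf <- build_stay_table(mf)
  for (tt in c("common", "rare")) {
    s_rew <- with(rows_mf, mean(stay[prev_outcome == "reward" &
                                       prev_transition == tt]))
    s_pun <- with(rows_mf, mean(stay[prev_outcome == "punishment" &
                                       prev_transition == tt]))
    expect_gt(s_rew, s_pun)
  }

  # zero temperatures: both stages near 50/50
  set.seed(23)
  noisy <- simulate_agent(hybrid_params(beta1 = 0, beta2 = 0, rep = 0),
                          task_config(n_trials = 2000))
  expect_lt(abs(mean(noisy$a1) - 0.5), 0.05)
  expect_lt(abs(mean(noisy$a2) - 0.5), 0.05)
})

test_that("the likelihood matches its closed form under the uniform policy", {
  set.seed(2)
  trials <- simulate_agent(hybrid_params(beta1 = 0, beta2 = 0, rep = 0),
                           task_config(n_trials = 201))
  nll <- negative_log_likelihood(
    hybrid_params(beta1 = 0, beta2 = 0, rep = 0), trials)
  expect_equal(nll, 402 * log(2), tolerance = 1e-12)
})

test_that("the compiled likelihood equals the naive oracle", {
  set.seed(14)
  for (k in 1:10) {
    par <- random_oracle_params()
    trials <- simulate_agent(do.call(hybrid_params, par),
                             task_config(n_trials = sample(30:90, 1)))
    expect_lt(
      abs(negative_log_likelihood(do.call(hybrid_params, par), trials) -
            oracle_nll(par, trials)),
      1e-8
    )
  }
})

test_that("every appended trial strictly increases the NLL", {
  set.seed(15)
  trials <- simulate_agent(hybrid_params(beta1 = 2), task_config(n_trials = 60))
  p <- hybrid_params(beta1 = 1.5, omega = 0.4)
  nlls <- vapply(c(20, 40, 60), function(n) {
    negative_log_likelihood(p, trials[1:n, ])
  }, numeric(1))
  expect_true(all(diff(nlls) > 0))
})

test_that("a model-free learner is blind to the transition mapping", {
  set.seed(16)
  trials <- simulate_agent(hybrid_params(beta1 = 2, omega = 0.5),
                           task_config(n_trials = 150))
  # consistently relabel the second-stage states (and transition labels)
  flipped <- trials
  flipped$s2 <- 1L - flipped$s2
  flipped$transition <- ifelse(flipped$s2 == flipped$a1, "common", "rare")
  p_mf <- hybrid_params(omega = 0, beta1 = 2, beta2 = 2, lam = 1)
  p_mb <- hybrid_params(omega = 1, beta1 = 2, beta2 = 2, lam = 1)
  expect_equal(negative_log_likelihood(p_mf, trials),
               negative_log_likelihood(p_mf, flipped), tolerance = 1e-12)
  expect_gt(abs(negative_log_likelihood(p_mb, trials) -
                  negative_log_likelihood(p_mb, flipped)), 1e-6)
})

test_that("malformed sequences are rejected with the offending trial named", {
  set.seed(17)
  trials <- simulate_agent(hybrid_params(), task_config(n_trials = 20))
  shuffled <- trials[c(2, 1, 3:20), ]
  expect_error(negative_log_likelihood(hybrid_params(), shuffled),
               "ordered")
  two_subj <- dplyr::bind_rows(trials,
                               dplyr::mutate(trials, subject = "other"))
  expect_error(negative_log_likelihood(hybrid_params(), two_subj),
               "single subject")
})
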