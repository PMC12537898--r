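#' Parameters of the hybrid model-free/model-based learner
#'
#' The hybrid learner runs a model-free SARSA(lambda) value learner alongside
#' a model-based planner that evaluates first-stage actions through the known
#' transition structure. The mixture weight `omega` sets the balance:
#' `omega = 1` is pure model-based, `omega = 0` pure model-free control.
#'
#' @param alpha1,alpha2 First- and second-stage learning rates in \[0, 1\].
#' @param lam Eligibility-trace parameter lambda in \[0, 1\]; the second-stage
#'   prediction error updates the first-stage model-free value with weight
#'   `alpha1 * lam`.
#' @param beta1,beta2 Nonnegative inverse temperatures of the stage-1 and
#'   stage-2 softmax. Payoffs enter the likelihood unscaled (points between
#'   -5 and +5), so betas live on a smaller numeric scale than in
#'   binary-reward tasks.
#' @param omega Model-based weight in \[0, 1\].
#' @param rep First-stage choice-repetition (perseveration) bonus in logit
#'   units; added to the value of the previously chosen first-stage action.
#'
#' @return A named list with class `hybrid_params`.
#' @examples
#' hybrid_params(omega = 0.8)
#' @export
hybrid_params <- function(alpha1 = 0.5, alpha2 = 0.5, lam = 0.5,
                          beta1 = 1, beta2 = 1, omega = 0.5, rep = 0) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, lam = lam,
            beta1 = beta1, beta2 = beta2, omega = omega, rep = rep)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L)))) {
    stop("All hybrid parameters must be single finite numbers.", call. = FALSE)
  }
  for (nm in c("alpha1", "alpha2", "lam", "omega")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1].", call. = FALSE)
    }
  }
  for (nm in c("beta1", "beta2")) {
    if (p[[nm]] < 0) stop("`", nm, "` must be nonnegative.", call. = FALSE)
  }
  structure(p, class = "hybrid_params")
}

#' @exportS3Method base::print
print.hybrid_params <- function(x, ...) {
  cat("<hybrid_params>\n")
  print(round(unlist(unclass(x)), 4))
  invisible(x)
}

#' Write and read hybrid parameters as JSON
#'
#' Parameters are stored as a flat named JSON object; reading re-validates
#' every bound through [hybrid_params()].
#'
#' @param params A [hybrid_params()].
#' @param path File path.
#' @return `write_hybrid_params()` returns `path` invisibly;
#'   `read_hybrid_params()` returns a validated [hybrid_params()].
#' @export
write_hybrid_params <- function(params, path) {
  params <- as_hybrid_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hybrid_params
#' @export
read_hybrid_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_fields <- setdiff(names(formals(hybrid_params)), names(raw))
  if (length(missing_fields) > 0L) {
    stop("Parameter file is missing field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  do.call(hybrid_params, raw[names(formals(hybrid_params))])
}

as_hybrid_params <- function(x) {
  if (inherits(x, "hybrid_params")) return(x)
  do.call(hybrid_params, as.list(x)[names(formals(hybrid_params))])
}

#' Model-based first-stage action values
#'
#' Evaluates each first-stage action prospectively through the transition
#' model: the value of action `a` is the probability-weighted best
#' second-stage value, `p_common * max_a' q2(common(a), a') +
#' (1 - p_common) * max_a' q2(other(a), a')`.
#'
#' @param q2 A 2 x 2 matrix of second-stage action values (state x action).
#' @param p_common Common-transition probability.
#' @return Numeric vector of length 2 (value of first-stage actions 0 and 1).
#' @examples
#' mb_values(matrix(c(1, 3, 2, 4), 2), p_common = 0.7)
#' @export
mb_values <- function(q2, p_common = 0.7) {
  stopifnot(is.matrix(q2), all(dim(q2) == 2L), all(is.finite(q2)))
  best <- c(max(q2[1L, ]), max(q2[2L, ]))
  c(p_common * best[1L] + (1 - p_common) * best[2L],
    p_common * best[2L] + (1 - p_common) * best[1L])
}

#' Softmax choice probabilities with a perseveration bonus
#'
#' Overflow-safe softmax over `beta * values` plus `rep` added to the action
#' equal to `prev_a1` (first stage only; pass `prev_a1 = NULL` or `rep = 0`
#' for the second stage).
#'
#' @param values Numeric vector of length 2 (net action values).
#' @param beta Nonnegative inverse temperature.
#' @param prev_a1 Previous first-stage action (0/1) or `NULL` on trial 1.
#' @param rep Repetition bonus in logit units.
#' @return Probabilities of actions 0 and 1 (sums to 1).
#' @examples
#' choice_probabilities(c(2.6, 3.4), beta = 1)
#' @export
choice_probabilities <- function(values, beta, prev_a1 = NULL, rep = 0) {
  stopifnot(length(values) == 2L, all(is.finite(values)), beta >= 0)
  x <- beta * values
  if (!is.null(prev_a1) && rep != 0) {
    x[prev_a1 + 1L] <- x[prev_a1 + 1L] + rep
  }
  x <- x - max(x)
  exp(x) / sum(exp(x))
}

new_latent_values <- function() {
  list(q_mf1 = c(0, 0), q2 = matrix(0, 2L, 2L))
}

latent_with_mb <- function(latent, params, p_common) {
  latent$q_mb1 <- mb_values(latent$q2, p_common)
  latent$q_net1 <- params$omega * latent$q_mb1 +
    (1 - params$omega) * latent$q_mf1
  latent
}

#' One learning update of the hybrid model
#'
#' Applies the SARSA(lambda)-style update for a completed trial: the
#' first-stage model-free value of the chosen action moves toward the
#' second-stage value (prediction error `delta1`), the second-stage value
#' moves toward the delivered points (`delta2`), and `delta2` additionally
#' updates the first-stage value with weight `alpha1 * lam`. Model-based
#' first-stage values are recomputed from the updated second-stage values.
#'
#' @param latent List with elements `q_mf1` (length-2) and `q2` (2 x 2).
#' @param trial One-row list/data frame with `a1`, `s2`, `a2`, `points`
#'   (0/1 codes).
#' @param params A [hybrid_params()].
#' @param p_common Common-transition probability (for the model-based values).
#' @return The updated latent list, with `q_mb1`, `q_net1`, and the two
#'   prediction errors `delta1`, `delta2` attached.
#' @export
update_values <- function(latent, trial, params, p_common = 0.7) {
  params <- as_hybrid_params(params)
  a1 <- trial$a1 + 1L
  s2 <- trial$s2 + 1L
  a2 <- trial$a2 + 1L
  delta1 <- latent$q2[s2, a2] - latent$q_mf1[a1]
  latent$q_mf1[a1] <- latent$q_mf1[a1] + params$alpha1 * delta1
  delta2 <- trial$points - latent$q2[s2, a2]
  latent$q2[s2, a2] <- latent$q2[s2, a2] + params$alpha2 * delta2
  latent$q_mf1[a1] <- latent$q_mf1[a1] + params$alpha1 * params$lam * delta2
  latent <- latent_with_mb(latent, params, p_common)
  latent$delta1 <- delta1
  latent$delta2 <- delta2
  latent
}

#' Simulate a hybrid agent on the two-step task
#'
#' Samples choices from the agent's own softmax policies, transitions and
#' payoffs from the task environment, and learns trial by trial.
#'
#' @param params A [hybrid_params()].
#' @param config A [task_config()].
#' @param walks Optional pre-generated [generate_payoff_walks()] output; fresh
#'   walks are generated when `NULL`.
#' @param subject Subject identifier stored in the output.
#' @return A trials tibble (see [write_trials()] for the schema).
#' @examples
#' set.seed(1)
#' simulate_agent(hybrid_params(omega = 1, beta1 = 2), task_config(n_trials = 20))
#' @export
simulate_agent <- function(params, config = task_config(), walks = NULL,
                           subject = "s1") {
  params <- as_hybrid_params(params)
  stopifnot(inherits(config, "task_config"))
  if (is.null(walks)) walks <- generate_payoff_walks(config)
  stopifnot(inherits(walks, "payoff_walks"),
            dim(walks$values)[1L] >= config$n_trials)
  n <- config$n_trials
  latent <- latent_with_mb(new_latent_values(), params, config$p_common)
  prev_a1 <- NULL
  a1 <- s2 <- a2 <- integer(n)
  transition <- character(n)
  points <- numeric(n)
  for (t in seq_len(n)) {
    p1 <- choice_probabilities(latent$q_net1, params$beta1, prev_a1,
                               params$rep)
    a1[t] <- as.integer(runif(1) < p1[2L])
    tr <- sample_transition(a1[t], config)
    s2[t] <- tr$s2
    transition[t] <- tr$transition
    p2 <- choice_probabilities(latent$q2[s2[t] + 1L, ], params$beta2)
    a2[t] <- as.integer(runif(1) < p2[2L])
    points[t] <- walks$values[t, s2[t] + 1L, a2[t] + 1L]
    latent <- update_values(
      latent, list(a1 = a1[t], s2 = s2[t], a2 = a2[t], points = points[t]),
      params, config$p_common
    )
    prev_a1 <- a1[t]
  }
  tibble::tibble(
    subject = subject, trial = seq_len(n), a1 = a1,
    transition = transition, s2 = s2, a2 = a2, points = points
  )
}

check_trial_sequence <- function(trials) {
  validate_trials(trials)
  if (length(unique(trials$subject)) != 1L) {
    stop("Expected trials from a single subject.", call. = FALSE)
  }
  if (is.unsorted(trials$trial, strictly = TRUE)) {
    stop("Trials must be strictly ordered by trial index; problem near trial ",
         trials$trial[which(diff(trials$trial) <= 0)[1L] + 1L], ".",
         call. = FALSE)
  }
  trials
}

#' Negative log-likelihood of a trial sequence under the hybrid model
#'
#' Sums `-log p(a1) - log p(a2)` over trials, updating values in sequence
#' exactly as [update_values()] does. The recursion runs in compiled code.
#'
#' @param params A [hybrid_params()] (or named list/vector coercible to one).
#' @param trials Trials tibble of one subject, ordered by trial.
#' @param p_common Common-transition probability of the task.
#' @return The scalar negative log-likelihood.
#' @examples
#' set.seed(1)
#' tr <- simulate_agent(hybrid_params(), task_config(n_trials = 30))
#' negative_log_likelihood(hybrid_params(), tr)
#' @export
negative_log_likelihood <- function(params, trials, p_common = 0.7) {
  params <- as_hybrid_params(params)
  check_trial_sequence(trials)
  hybrid_nll_cpp(
    as.integer(trials$a1), as.integer(trials$s2), as.integer(trials$a2),
    as.numeric(trials$points),
    params$alpha1, params$alpha2, params$lam,
    params$beta1, params$beta2, params$omega, params$rep, p_common
  )
}
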