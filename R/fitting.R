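# parameter transforms between the constrained space and the unconstrained
# optimisation space: logit for unit-interval parameters, log for betas,
# identity for the repetition bonus

unit_params <- c("alpha1", "alpha2", "lam", "omega")
pos_params <- c("beta1", "beta2")
param_names <- c(unit_params, pos_params, "rep")

to_unconstrained <- function(params) {
  p <- unlist(unclass(as_hybrid_params(params)))[param_names]
  eta <- p
  eta[unit_params] <- qlogis(pmin(pmax(p[unit_params], 1e-9), 1 - 1e-9))
  eta[pos_params] <- log(pmax(p[pos_params], 1e-9))
  eta
}

from_unconstrained <- function(eta) {
  p <- setNames(eta, param_names)
  p[unit_params] <- plogis(p[unit_params])
  p[pos_params] <- exp(p[pos_params])
  do.call(hybrid_params, as.list(p))
}

#' Weakly informative priors for MAP fitting
#'
#' Beta(1.1, 1.1) on unit-interval parameters, Gamma(shape 1.2, rate 0.2) on
#' the inverse temperatures, Normal(0, 1) on the repetition bonus. Returns the
#' log prior density at the given (constrained) parameters.
#'
#' @param params A [hybrid_params()].
#' @return Scalar log prior density.
#' @export
hybrid_log_prior <- function(params) {
  p <- as_hybrid_params(params)
  sum(stats::dbeta(unlist(p[unit_params]), 1.1, 1.1, log = TRUE)) +
    sum(stats::dgamma(unlist(p[pos_params]), shape = 1.2, rate = 0.2,
                      log = TRUE)) +
    stats::dnorm(p$rep, 0, 1, log = TRUE)
}

penalized_nll <- function(params, trials, p_common) {
  negative_log_likelihood(params, trials, p_common) - hybrid_log_prior(params)
}

# random start in unconstrained space, drawn from the priors (betas truncated
# away from 0 so starts are not degenerate)
random_start <- function() {
  c(qlogis(rbeta(4L, 1.1, 1.1) * 0.98 + 0.01),
    log(pmax(rgamma(2L, shape = 1.2, rate = 0.2), 0.05)),
    rnorm(1L))
}

apply_constraints <- function(eta, constraints) {
  if ("single_alpha" %in% constraints) eta[2L] <- eta[1L]
  if ("single_beta" %in% constraints) eta[6L] <- eta[5L]
  eta
}

n_free_params <- function(constraints) {
  7L - ("single_alpha" %in% constraints) - ("single_beta" %in% constraints)
}

#' Fit the hybrid model to one subject by MAP
#'
#' Minimises the penalised negative log-likelihood (NLL minus log prior) in
#' unconstrained (logit/log) space with multiple random restarts
#' (Nelder-Mead, then a BFGS polish of the best restart). Reduced model
#' variants share the learning rate and/or inverse temperature across stages.
#'
#' @param trials Trials tibble of one subject.
#' @param p_common Common-transition probability of the task.
#' @param n_restarts Number of random restarts (default 10).
#' @param constraints Character vector; any of `"single_alpha"`,
#'   `"single_beta"` to share parameters across stages (the model-comparison
#'   set).
#' @param prior Logical; `FALSE` fits by plain maximum likelihood.
#' @return A list of class `hybrid_fit` with elements `params`, `nll`
#'   (unpenalised NLL at the optimum), `penalized_nll`,
#'   `n_restarts_converged`, `hessian_ok`, `converged`, `n_trials`,
#'   `constraints`.
#' @examples
#' set.seed(1)
#' tr <- simulate_agent(hybrid_params(beta1 = 2, beta2 = 2),
#'                      task_config(n_trials = 80))
#' fit <- fit_subject(tr, n_restarts = 3)
#' tidy(fit)
#' @export
fit_subject <- function(trials, p_common = 0.7, n_restarts = 10L,
                        constraints = character(), prior = TRUE) {
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("Cannot fit an empty trial set.", call. = FALSE)
  }
  check_trial_sequence(trials)
  if (nrow(trials) < 50L) {
    warning("Fewer than 50 trials; parameter estimates will be unstable.",
            call. = FALSE)
  }
  stopifnot(all(constraints %in% c("single_alpha", "single_beta")))

  # hot path: transform, likelihood and prior inlined (validation done once)
  a1 <- as.integer(trials$a1)
  s2 <- as.integer(trials$s2)
  a2 <- as.integer(trials$a2)
  r <- as.numeric(trials$points)
  objective <- function(eta) {
    eta <- apply_constraints(eta, constraints)
    unit <- plogis(eta[c(1L, 2L, 3L, 4L)])
    pos <- exp(eta[c(5L, 6L)])
    val <- hybrid_nll_cpp(a1, s2, a2, r, unit[1L], unit[2L], unit[3L],
                          pos[1L], pos[2L], unit[4L], eta[7L], p_common)
    if (prior) {
      val <- val - sum(stats::dbeta(unit, 1.1, 1.1, log = TRUE)) -
        sum(stats::dgamma(pos, shape = 1.2, rate = 0.2, log = TRUE)) -
        stats::dnorm(eta[7L], 0, 1, log = TRUE)
    }
    if (!is.finite(val)) val <- 1e10
    val
  }

  best <- NULL
  n_converged <- 0L
  for (k in seq_len(n_restarts)) {
    start <- random_start()
    opt <- tryCatch(
      optim(start, objective, method = "Nelder-Mead",
            control = list(maxit = 4000L, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (opt$convergence == 0L) n_converged <- n_converged + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("All restarts failed for this subject.", call. = FALSE)
  }
  polish <- tryCatch(
    optim(best$par, objective, method = "BFGS",
          control = list(maxit = 500L, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  hess_ok <- tryCatch({
    h <- stats::optimHess(best$par, objective)
    all(is.finite(h)) && all(eigen(h, symmetric = TRUE,
                                   only.values = TRUE)$values > 0)
  }, error = function(e) FALSE)

  params <- from_unconstrained(apply_constraints(best$par, constraints))
  fit <- structure(
    list(
      params = params,
      nll = negative_log_likelihood(params, trials, p_common),
      penalized_nll = best$value,
      n_restarts_converged = n_converged,
      hessian_ok = hess_ok,
      converged = n_converged > 0L,
      n_trials = nrow(trials),
      n_free_params = n_free_params(constraints),
      constraints = constraints,
      p_common = p_common,
      subject = trials$subject[1L]
    ),
    class = "hybrid_fit"
  )
  if (!fit$converged) {
    warning("No restart reported convergence for subject ", fit$subject,
            "; result flagged.", call. = FALSE)
  }
  fit
}

#' @exportS3Method base::print
print.hybrid_fit <- function(x, ...) {
  cat("<hybrid_fit> subject", x$subject, "-", x$n_trials, "trials, NLL =",
      round(x$nll, 2), if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  print(round(unlist(unclass(x$params)), 3))
  invisible(x)
}

#' @rdname fit_subject
#' @param x A `hybrid_fit`.
#' @param ... Unused.
#' @export
tidy.hybrid_fit <- function(x, ...) {
  tibble::tibble(
    subject = x$subject,
    term = param_names,
    estimate = unlist(unclass(x$params))[param_names]
  )
}

#' @rdname fit_subject
#' @export
glance.hybrid_fit <- function(x, ...) {
  k <- x$n_free_params
  tibble::tibble(
    nll = x$nll, penalized_nll = x$penalized_nll,
    AIC = 2 * x$nll + 2 * k,
    BIC = 2 * x$nll + k * log(2L * x$n_trials),
    n_trials = x$n_trials, converged = x$converged,
    hessian_ok = x$hessian_ok
  )
}

#' Fit the hybrid model to every subject in a trials table
#'
#' @param trials Trials tibble (multiple subjects).
#' @inheritParams fit_subject
#' @return A tibble with one row per subject: fitted parameters, NLL, and
#'   convergence flags.
#' @export
fit_hybrid <- function(trials, p_common = 0.7, n_restarts = 10L,
                       constraints = character(), prior = TRUE) {
  validate_trials(trials)
  trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(df, key) {
      fit <- fit_subject(
        dplyr::mutate(df, subject = key$subject),
        p_common = p_common, n_restarts = n_restarts,
        constraints = constraints, prior = prior
      )
      dplyr::bind_cols(
        tibble::tibble(subject = key$subject),
        tibble::as_tibble(unclass(fit$params)),
        tibble::tibble(nll = fit$nll, converged = fit$converged,
                       hessian_ok = fit$hessian_ok)
      )
    }) |>
    dplyr::bind_rows()
}
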