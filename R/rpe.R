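#' Decompose reward prediction errors into model-free and model-based parts
#'
#' Replays a trial sequence under given parameters and records, per trial, two
#' events: the second-stage onset, where the model-free system compares the
#' entered second-stage value against the cached first-stage value
#' (`delta_mf = q2(s2, a2) - q_mf1(a1)`) while the model-based system compares
#' it against its prospective value (`delta_mb = q2(s2, a2) - q_mb1(a1)`); and
#' the outcome, where both systems share the same error `r - q2(s2, a2)`. The
#' unique model-based component is `delta_unique = delta_mb - delta_mf`; it is
#' identically zero at outcome events.
#'
#' @param params A [hybrid_params()]; `omega`, `beta1`, `beta2` and `rep` do
#'   not enter the error terms but are accepted for a uniform interface.
#' @param trials Trials tibble of one subject, ordered by trial.
#' @param p_common Common-transition probability.
#' @return A tibble with columns `subject, trial, event` (`"onset2"` /
#'   `"outcome"`), `delta_mf`, `delta_mb`, `delta_unique`, two rows per trial.
#' @examples
#' set.seed(1)
#' tr <- simulate_agent(hybrid_params(), task_config(n_trials = 10))
#' decompose_rpes(hybrid_params(alpha1 = 0.5, alpha2 = 0.5, lam = 1), tr)
#' @export
decompose_rpes <- function(params, trials, p_common = 0.7) {
  params <- as_hybrid_params(params)
  check_trial_sequence(trials)
  n <- nrow(trials)
  latent <- latent_with_mb(new_latent_values(), params, p_common)
  d_mf <- d_mb <- d_out <- numeric(n)
  for (t in seq_len(n)) {
    a1 <- trials$a1[t] + 1L
    s2 <- trials$s2[t] + 1L
    a2 <- trials$a2[t] + 1L
    q2_sa <- latent$q2[s2, a2]
    d_mf[t] <- q2_sa - latent$q_mf1[a1]
    d_mb[t] <- q2_sa - latent$q_mb1[a1]
    d_out[t] <- trials$points[t] - q2_sa
    latent <- update_values(latent, trials[t, ], params, p_common)
  }
  onset <- tibble::tibble(
    subject = trials$subject, trial = trials$trial, event = "onset2",
    delta_mf = d_mf, delta_mb = d_mb, delta_unique = d_mb - d_mf
  )
  outcome <- tibble::tibble(
    subject = trials$subject, trial = trials$trial, event = "outcome",
    delta_mf = d_out, delta_mb = d_out, delta_unique = 0
  )
  dplyr::arrange(dplyr::bind_rows(onset, outcome), .data$trial,
                 dplyr::desc(.data$event == "onset2"))
}

#' Export per-trial prediction-error modulators
#'
#' Writes the RPE series as CSV with columns
#' `subject, trial, event, delta_mf, delta_mb, delta_unique`. Concatenating
#' both event streams corresponds to modulators on a combined
#' second-stage/outcome onset regressor.
#'
#' @param rpes Output of [decompose_rpes()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_rpes <- function(rpes, path) {
  stopifnot(all(c("subject", "trial", "event", "delta_mf", "delta_mb",
                  "delta_unique") %in% names(rpes)))
  readr::write_csv(rpes, path)
  invisible(path)
}
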