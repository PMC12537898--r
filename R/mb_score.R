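#' Build the stay/switch table from trial records
#'
#' For trials 2..n of each subject, records whether the first-stage choice was
#' repeated (`stay`), together with the previous trial's outcome (reward =
#' positive points, punishment = negative) and transition type. Outcome and
#' transition are effect-coded (+0.5 reward/common, -0.5
#' punishment/rare). Subjects with fewer than two trials are excluded with a
#' message.
#'
#' @param trials Trials tibble (any number of subjects).
#' @return A tibble with columns `subject, trial, stay, prev_outcome,
#'   prev_transition, outcome, transition, trial_scaled` (the last three
#'   numeric codes; `trial_scaled` is the within-subject standardised trial
#'   number, for the optional regression correction).
#' @examples
#' set.seed(1)
#' tr <- simulate_agent(hybrid_params(), task_config(n_trials = 10))
#' build_stay_table(tr)
#' @export
build_stay_table <- function(trials) {
  validate_trials(trials)
  n_per <- table(trials$subject)
  drop <- names(n_per)[n_per < 2L]
  if (length(drop) > 0L) {
    message("Excluding ", length(drop),
            " subject(s) with a single trial: ",
            paste(drop, collapse = ", "))
    trials <- trials[!(trials$subject %in% drop), , drop = FALSE]
  }
  trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(
      stay = as.integer(.data$a1 == dplyr::lag(.data$a1)),
      prev_outcome = ifelse(dplyr::lag(.data$points) > 0,
                            "reward", "punishment"),
      prev_transition = dplyr::lag(.data$transition),
      trial_scaled = as.numeric(scale(.data$trial))
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$stay)) |>
    dplyr::transmute(
      .data$subject, .data$trial, .data$stay,
      .data$prev_outcome, .data$prev_transition,
      outcome = ifelse(.data$prev_outcome == "reward", 0.5, -0.5),
      transition = ifelse(.data$prev_transition == "common", 0.5, -0.5),
      .data$trial_scaled
    )
}

#' Logistic mixed-effects model of stay/switch behaviour
#'
#' Fits `stay ~ outcome * transition` with by-subject random intercepts and
#' slopes for all within-subject terms (uncorrelated). The previous-outcome x
#' previous-transition interaction indexes model-based behaviour: a
#' model-based learner stays after rewarded common and punished rare
#' transitions, a model-free learner stays after reward regardless of
#' transition. The per-subject MB score is the fixed interaction effect plus
#' the subject's conditional-mode (shrinkage) deviation.
#'
#' @param rows Output of [build_stay_table()] (>= 2 subjects).
#' @param correction Logical; add the within-subject standardised trial
#'   number as a fixed covariate (regression correction; default `FALSE`).
#' @return A list of class `stay_fit` with elements `fixed` (tibble: term,
#'   estimate, std_error, z, p), `mb_scores` (tibble: subject, mb_score, se),
#'   `model` (the `glmerMod`), `random_structure`, `converged`.
#' @examples
#' \donttest{
#' set.seed(1)
#' trials <- purrr::map(1:6, function(i)
#'   simulate_agent(hybrid_params(omega = runif(1), beta1 = 2),
#'                  task_config(n_trials = 80), subject = paste0("s", i))) |>
#'   dplyr::bind_rows()
#' fit <- fit_stay_glmm(build_stay_table(trials))
#' fit$fixed
#' }
#' @export
fit_stay_glmm <- function(rows, correction = FALSE) {
  stopifnot(all(c("subject", "stay", "outcome", "transition") %in%
                  names(rows)))
  if (length(unique(rows$subject)) < 2L) {
    stop("The stay/switch model needs at least 2 subjects.", call. = FALSE)
  }
  fixed <- "stay ~ outcome * transition"
  if (correction) fixed <- paste(fixed, "+ trial_scaled")
  forms <- c(
    full = paste(fixed, "+ (1 + outcome + transition + outcome:transition",
                 "|| subject)"),
    intercept = paste(fixed, "+ (1 | subject)")
  )
  model <- NULL
  used <- NA_character_
  for (nm in names(forms)) {
    fit_try <- tryCatch(
      suppressMessages(lme4::glmer(
        stats::as.formula(forms[[nm]]), data = rows, family = stats::binomial,
        control = lme4::glmerControl(optimizer = "bobyqa",
                                     calc.derivs = FALSE)
      )),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit_try)) {
      model <- fit_try
      used <- nm
      break
    }
  }
  if (is.null(model)) {
    # last resort: accept the full model with its warnings, flagged
    model <- suppressWarnings(suppressMessages(lme4::glmer(
      stats::as.formula(forms[["full"]]), data = rows,
      family = stats::binomial,
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE)
    )))
    used <- "full (not converged)"
  }
  sm <- summary(model)$coefficients
  fixed_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"]
  )
  inter <- fixed_tbl$estimate[fixed_tbl$term == "outcome:transition"]
  re <- lme4::ranef(model, condVar = FALSE)$subject
  if ("outcome:transition" %in% colnames(re)) {
    dev <- re[, "outcome:transition"]
  } else {
    dev <- rep(0, nrow(re))
  }
  mb_scores <- tibble::tibble(
    subject = rownames(re),
    mb_score = inter + dev,
    se = fixed_tbl$std_error[fixed_tbl$term == "outcome:transition"]
  )
  structure(
    list(fixed = fixed_tbl, mb_scores = mb_scores, model = model,
         random_structure = used,
         converged = !grepl("not converged", used)),
    class = "stay_fit"
  )
}

#' @exportS3Method base::print
print.stay_fit <- function(x, ...) {
  cat("<stay_fit> logistic mixed model of stay/switch behaviour",
      sprintf("(random structure: %s)\n", x$random_structure))
  print(x$fixed)
  invisible(x)
}

#' @rdname fit_stay_glmm
#' @param x A `stay_fit`.
#' @param ... Unused.
#' @export
tidy.stay_fit <- function(x, ...) x$fixed

#' @rdname fit_stay_glmm
#' @export
glance.stay_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = stats::nobs(x$model),
    n_subjects = nrow(x$mb_scores),
    logLik = as.numeric(logLik(x$model)),
    AIC = AIC(x$model),
    converged = x$converged
  )
}

#' Stay probabilities by previous outcome and transition
#'
#' The canonical two-step behavioural signature: a bar chart of the
#' probability of repeating the first-stage choice, split by previous outcome
#' (reward/punishment) and previous transition (common/rare).
#'
#' @param trials Trials tibble.
#' @return A ggplot object.
#' @export
plot_stay_probabilities <- function(trials) {
  rows <- build_stay_table(trials)
  summ <- rows |>
    dplyr::group_by(.data$prev_outcome, .data$prev_transition) |>
    dplyr::summarise(p_stay = mean(.data$stay), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$prev_outcome,
                                     y = .data$p_stay,
                                     fill = .data$prev_transition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "previous outcome", y = "P(stay)",
                  fill = "previous transition") +
    ggplot2::theme_minimal()
}
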