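random_structures <- c("intercept", "slopes_uncorrelated",
                       "slopes_correlated")

random_term <- function(structure) {
  switch(structure,
    intercept = "(1 | subject)",
    slopes_uncorrelated =
      "(1 | subject) + (0 + int_no_more | subject) + (0 + int_less | subject)",
    slopes_correlated = "(1 + int_no_more + int_less | subject)",
    stop("Unknown random structure '", structure, "'.", call. = FALSE)
  )
}

#' Assemble the analysis data set for the moderation models
#'
#' Joins valid daily records with subject traits, builds the dependent
#' variables (`log_grams = log(grams + 1)` and the drinking indicator
#' `drink = grams > 0`), and dummy-codes drinking intention with 'no specific
#' intention' as the reference (`int_less`: drink less vs none;
#' `int_no_more`: drink no more vs none). Trait covariates other than the
#' (bounded) model-based weight are z-standardised.
#'
#' @param daily Tibble from [restructure_ema()].
#' @param traits Tibble with `subject` and the trait columns used.
#' @param traits_terms Character vector of trait column names entering the
#'   model.
#' @param standardize Trait columns to z-standardise (default: all
#'   `traits_terms` except `omega` and `mb_score`).
#' @return The analysis tibble.
#' @export
build_moderation_data <- function(daily, traits,
                                  traits_terms = "omega",
                                  standardize = NULL) {
  stopifnot(all(c("subject", "day", "grams", "intention") %in% names(daily)))
  if ("valid" %in% names(daily)) daily <- daily[daily$valid, , drop = FALSE]
  missing_tr <- setdiff(traits_terms, names(traits))
  if (length(missing_tr) > 0L) {
    stop("Trait column(s) not found: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(standardize)) {
    standardize <- setdiff(traits_terms, c("omega", "mb_score"))
  }
  traits <- traits[c("subject", traits_terms)]
  for (col in standardize) {
    traits[[col]] <- as.numeric(scale(traits[[col]]))
  }
  dplyr::inner_join(daily, traits, by = "subject") |>
    dplyr::mutate(
      log_grams = log1p(.data$grams),
      drink = as.integer(.data$grams > 0),
      int_less = as.numeric(.data$intention == "less"),
      int_no_more = as.numeric(.data$intention == "no_more")
    )
}

moderation_formula <- function(dependent, traits_terms, structure) {
  lhs <- switch(dependent, log_grams = "log_grams",
                drink_indicator = "drink",
                stop("Unknown dependent '", dependent, "'.", call. = FALSE))
  fixed <- c("int_no_more", "int_less", traits_terms,
             paste0("int_no_more:", traits_terms),
             paste0("int_less:", traits_terms))
  stats::as.formula(paste(lhs, "~", paste(fixed, collapse = " + "), "+",
                          random_term(structure)))
}

fit_mixed <- function(formula, data, family) {
  if (is.null(family)) {
    lme4::lmer(formula, data = data, REML = FALSE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           calc.derivs = FALSE))
  } else {
    lme4::glmer(formula, data = data, family = family,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))
  }
}

varcorr_tibble <- function(model) {
  vc <- as.data.frame(lme4::VarCorr(model))
  tibble::tibble(
    group = vc$grp, term1 = vc$var1, term2 = vc$var2,
    variance = vc$vcov, sd = vc$sdcor
  )
}

#' Mixed-effects moderation model of daily drinking by intention and traits
#'
#' Fits, by maximum likelihood, a linear mixed model of log daily grams
#' (incremented by 1) or a logistic mixed model of the drinking indicator,
#' with fixed effects for the two intention dummies ('drink less' and 'drink
#' no more' vs 'no specific intention'), the trait covariates, and all
#' trait-by-intention two-way interactions; subject random effects per
#' `structure`. The cross-level interactions `int_less:trait` carry the
#' moderation question: does the trait sharpen the within-subject consumption
#' drop on reduction-intention days?
#'
#' @param daily Tibble from [restructure_ema()].
#' @param traits Tibble of subject traits.
#' @param dependent `"log_grams"` (LMM) or `"drink_indicator"` (logistic
#'   GLMM).
#' @param traits_terms Trait column names (e.g. `"omega"` or
#'   `c("omega", "sig_hippocampus", "sig_vs", "sig_vmpfc")`).
#' @param structure Random-effects structure: `"intercept"`,
#'   `"slopes_uncorrelated"` (default) or `"slopes_correlated"`.
#' @param ci_method `"wald"` (default) or `"profile"` (LMM only; slower).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `moderation_fit`: `coefficients` (term, estimate,
#'   std_error, statistic, df, p, conf_low, conf_high, and `odds_ratio` for
#'   the GLMM), `varcomp`, `model`, `spec`, `converged`, `separation_flag`,
#'   `n_obs`, `n_subjects`.
#' @examples
#' \donttest{
#' set.seed(1)
#' cohort <- simulate_ema_cohort(ema_config(n_subjects = 20, horizon = 120))
#' daily <- restructure_ema(cohort$ratings, cohort$reports)
#' fit <- fit_moderation(daily, cohort$traits)
#' tidy(fit)
#' }
#' @export
fit_moderation <- function(daily, traits, dependent = "log_grams",
                           traits_terms = "omega",
                           structure = "slopes_uncorrelated",
                           ci_method = c("wald", "profile"),
                           conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  structure <- match.arg(structure, random_structures)
  data <- build_moderation_data(daily, traits, traits_terms)
  if (length(unique(data$subject)) < 10L) {
    warning("Fewer than 10 subjects; moderation estimates will be fragile.",
            call. = FALSE)
  }
  present <- intention_levels %in% unique(data$intention)
  if (!all(present)) {
    warning("Intention category(ies) never observed: ",
            paste(intention_levels[!present], collapse = ", "),
            call. = FALSE)
  }
  family <- if (dependent == "drink_indicator") stats::binomial() else NULL
  is_glmm <- !is.null(family)

  separation_flag <- is_glmm &&
    (all(data$drink == 1L) || all(data$drink == 0L))
  if (separation_flag) {
    warning("Drinking indicator is constant; logistic model is separated.",
            call. = FALSE)
  }

  model <- NULL
  used_structure <- structure
  converged <- TRUE
  for (st in unique(c(structure, "intercept"))) {
    formula <- moderation_formula(dependent, traits_terms, st)
    res <- withCallingHandlers(
      tryCatch(fit_mixed(formula, data, family), error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!inherits(res, "error")) {
      ok <- length(res@optinfo$conv$lme4) == 0L &&
        res@optinfo$conv$opt == 0L
      model <- res
      used_structure <- st
      converged <- ok
      if (ok) break
      # keep the non-converged fit but try the simpler structure
    }
  }
  if (is.null(model) && separation_flag) {
    # a constant indicator carries no information; return a flagged stub
    return(structure(
      list(coefficients = tibble::tibble(), varcomp = tibble::tibble(),
           model = NULL,
           spec = list(dependent = dependent, traits_terms = traits_terms,
                       structure = structure, requested = structure,
                       ci_method = ci_method, conf_level = conf_level),
           converged = FALSE, separation_flag = TRUE,
           n_obs = nrow(data), n_subjects = length(unique(data$subject)),
           logLik = NA_real_, trait_ranges = list(), data = data),
      class = "moderation_fit"
    ))
  }
  if (is.null(model)) {
    stop("Moderation model could not be fitted under any random structure.",
         call. = FALSE)
  }
  if (used_structure != structure) {
    warning("Random structure simplified to '", used_structure,
            "' after convergence failure.", call. = FALSE)
  }

  sm <- summary(model)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  n_obs <- stats::nobs(model)
  alpha <- 1 - conf_level
  if (is_glmm) {
    stat <- est / se
    df <- rep(Inf, length(est))
    p <- 2 * pnorm(-abs(stat))
    crit <- stats::qnorm(1 - alpha / 2)
  } else {
    df <- rep(n_obs - length(est), length(est))
    stat <- est / se
    p <- 2 * pt(-abs(stat), df)
    crit <- stats::qt(1 - alpha / 2, df[1L])
  }
  conf_low <- est - crit * se
  conf_high <- est + crit * se
  if (!is_glmm && ci_method == "profile") {
    prof <- tryCatch(
      suppressMessages(stats::confint(model, parm = "beta_",
                                      method = "profile",
                                      level = conf_level)),
      error = function(e) NULL
    )
    if (!is.null(prof)) {
      conf_low <- prof[, 1L]
      conf_high <- prof[, 2L]
    } else {
      warning("Profile CIs unavailable; falling back to Wald.",
              call. = FALSE)
    }
  }
  coefficients <- tibble::tibble(
    term = rownames(sm), estimate = est, std_error = se,
    statistic = stat, df = df, p = p,
    conf_low = conf_low, conf_high = conf_high
  )
  if (is_glmm) {
    coefficients$odds_ratio <- exp(coefficients$estimate)
  }
  structure(
    list(coefficients = coefficients, varcomp = varcorr_tibble(model),
         model = model,
         spec = list(dependent = dependent, traits_terms = traits_terms,
                     structure = used_structure, requested = structure,
                     ci_method = ci_method, conf_level = conf_level),
         converged = converged, separation_flag = separation_flag,
         n_obs = n_obs, n_subjects = length(unique(data$subject)),
         logLik = as.numeric(logLik(model)),
         trait_ranges = purrr::map(
           setNames(traits_terms, traits_terms),
           function(tt) range(data[[tt]])
         ),
         data = data),
    class = "moderation_fit"
  )
}

#' Logistic mixed model of daily drinking versus abstinence
#'
#' Convenience wrapper for [fit_moderation()] with the drinking indicator
#' (grams > 0 vs grams = 0) as dependent variable; identical fixed and random
#' structure.
#'
#' @inheritParams fit_moderation
#' @return A `moderation_fit`.
#' @export
fit_glmm_drinking <- function(daily, traits, traits_terms = "omega",
                              structure = "slopes_uncorrelated",
                              conf_level = 0.95) {
  fit_moderation(daily, traits, dependent = "drink_indicator",
                 traits_terms = traits_terms, structure = structure,
                 conf_level = conf_level)
}

#' @exportS3Method base::print
print.moderation_fit <- function(x, ...) {
  cat("<moderation_fit>", x$spec$dependent, "~ intention x (",
      paste(x$spec$traits_terms, collapse = ", "), ")\n",
      "random structure:", x$spec$structure, "|", x$n_obs, "days,",
      x$n_subjects, "subjects",
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname fit_moderation
#' @param x A `moderation_fit`.
#' @param ... Unused.
#' @export
tidy.moderation_fit <- function(x, ...) x$coefficients

#' @rdname fit_moderation
#' @export
glance.moderation_fit <- function(x, ...) {
  tibble::tibble(
    dependent = x$spec$dependent, structure = x$spec$structure,
    n_obs = x$n_obs, n_subjects = x$n_subjects,
    logLik = x$logLik, AIC = AIC(x$model), BIC = BIC(x$model),
    converged = x$converged
  )
}

#' Select the random-effects structure by likelihood ratio test
#'
#' Fits the nested candidate sequence (random intercept; adding uncorrelated
#' intention slopes; adding their correlations) by maximum likelihood and
#' keeps the most complex structure that improves significantly (chi-square
#' LRT, p < `alpha`) on its simpler neighbour.
#'
#' @inheritParams fit_moderation
#' @param alpha LRT significance level (default 0.05).
#' @return A list with `structure` (chosen name) and `lrt` (tibble:
#'   comparison, df, chisq, p, plus fit notes for unidentifiable candidates).
#' @export
select_random_structure <- function(daily, traits, dependent = "log_grams",
                                    traits_terms = "omega", alpha = 0.05) {
  data <- build_moderation_data(daily, traits, traits_terms)
  family <- if (dependent == "drink_indicator") stats::binomial() else NULL
  fits <- purrr::map(random_structures, function(st) {
    formula <- moderation_formula(dependent, traits_terms, st)
    withCallingHandlers(
      tryCatch(fit_mixed(formula, data, family), error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  names(fits) <- random_structures
  ok <- !vapply(fits, inherits, logical(1L), "error")
  if (!ok[["intercept"]]) {
    stop("Even the random-intercept model failed: ",
         conditionMessage(fits[["intercept"]]), call. = FALSE)
  }
  chosen <- "intercept"
  rows <- list()
  for (k in 2:3) {
    simpler <- random_structures[k - 1L]
    complex <- random_structures[k]
    if (!ok[[complex]] || !ok[[simpler]]) {
      rows[[complex]] <- tibble::tibble(
        comparison = paste(complex, "vs", simpler),
        df = NA_real_, chisq = NA_real_, p = NA_real_,
        note = "unidentifiable or failed fit"
      )
      break
    }
    lrt <- anova(fits[[simpler]], fits[[complex]])
    rows[[complex]] <- tibble::tibble(
      comparison = paste(complex, "vs", simpler),
      df = lrt$Df[2L], chisq = lrt$Chisq[2L],
      p = lrt$`Pr(>Chisq)`[2L], note = ""
    )
    if (chosen == simpler && !is.na(lrt$`Pr(>Chisq)`[2L]) &&
        lrt$`Pr(>Chisq)`[2L] < alpha) {
      chosen <- complex
    } else {
      break
    }
  }
  list(structure = chosen, lrt = dplyr::bind_rows(rows))
}

#' Intra-class correlation from an unconditional model
#'
#' Fits the intercept-only linear mixed model of log(grams + 1) by maximum
#' likelihood and reports the share of variance between subjects; the
#' complement is the within-subject share (day-to-day fluctuation).
#'
#' @param daily Tibble from [restructure_ema()].
#' @return A one-row tibble: `icc`, `between_var`, `within_var`,
#'   `within_share`. `icc` is `NA` (with a message) when the total variance
#'   is zero.
#' @export
icc_unconditional <- function(daily) {
  if ("valid" %in% names(daily)) daily <- daily[daily$valid, , drop = FALSE]
  daily <- dplyr::mutate(daily, log_grams = log1p(.data$grams))
  if (stats::var(daily$log_grams) == 0) {
    message("Zero total variance; ICC undefined.")
    return(tibble::tibble(icc = NA_real_, between_var = 0, within_var = 0,
                          within_share = NA_real_))
  }
  model <- lme4::lmer(log_grams ~ 1 + (1 | subject), data = daily,
                      REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(model))
  between <- vc$vcov[vc$grp == "subject"]
  within <- vc$vcov[vc$grp == "Residual"]
  icc <- between / (between + within)
  tibble::tibble(icc = icc, between_var = between, within_var = within,
                 within_share = 1 - icc)
}

#' Model-implied marginal means per intention category
#'
#' Evaluates the fixed-effects linear predictor at specified trait values for
#' each intention category and back-transforms to the outcome scale:
#' `exp(m) - 1` grams for the log-gram LMM, a probability for the logistic
#' GLMM. Standard errors by the delta method on the link scale
#' (`sqrt(x' V x)`); confidence limits transformed from the link scale.
#'
#' @param fit A [fit_moderation()] result.
#' @param at Named list of trait values, e.g. `list(omega = c(0.2, 0.9))`;
#'   traits omitted default to their observed mean. Values outside the
#'   observed range trigger a warning.
#' @return A tibble: `intention`, one column per trait, `response` (grams or
#'   probability), `se_link`, `conf_low`, `conf_high`.
#' @export
marginal_means <- function(fit, at = list()) {
  stopifnot(inherits(fit, "moderation_fit"))
  traits_terms <- fit$spec$traits_terms
  for (nm in names(at)) {
    if (!nm %in% traits_terms) {
      stop("`at` refers to unknown trait '", nm, "'.", call. = FALSE)
    }
    rng <- fit$trait_ranges[[nm]]
    if (any(at[[nm]] < rng[1L] | at[[nm]] > rng[2L])) {
      warning("Values of '", nm, "' outside the observed range [",
              round(rng[1L], 3), ", ", round(rng[2L], 3),
              "]; extrapolating.", call. = FALSE)
    }
  }
  defaults <- purrr::map(setNames(traits_terms, traits_terms),
                         function(tt) mean(fit$data[[tt]]))
  grid_args <- c(list(intention = intention_levels),
                 utils::modifyList(defaults, as.list(at)))
  grid <- do.call(tidyr::crossing, grid_args)
  grid$int_less <- as.numeric(grid$intention == "less")
  grid$int_no_more <- as.numeric(grid$intention == "no_more")

  terms <- fit$coefficients$term
  X <- matrix(0, nrow(grid), length(terms), dimnames = list(NULL, terms))
  col_value <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
    out <- rep(1, nrow(grid))
    for (pp in parts) {
      if (pp == "(Intercept)") next
      out <- out * grid[[pp]]
    }
    out
  }
  for (term in terms) X[, term] <- col_value(term)
  beta <- fit$coefficients$estimate
  V <- as.matrix(vcov(fit$model))[terms, terms]
  m <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  alpha <- 1 - fit$spec$conf_level
  crit <- if (fit$spec$dependent == "drink_indicator") {
    stats::qnorm(1 - alpha / 2)
  } else {
    stats::qt(1 - alpha / 2, fit$n_obs - length(beta))
  }
  back <- if (fit$spec$dependent == "drink_indicator") plogis else expm1
  out <- grid[c("intention", traits_terms)]
  out$link <- m
  out$response <- back(m)
  out$se_link <- se
  out$conf_low <- back(m - crit * se)
  out$conf_high <- back(m + crit * se)
  tibble::as_tibble(out)
}

#' Partial-effect plot of the intention-by-trait moderation
#'
#' Predicted outcome against a trait, one line per intention category,
#' evaluated over the observed trait range with other traits at their means.
#'
#' @param object A `moderation_fit`.
#' @param trait Trait to display on the x axis (default first).
#' @param n_points Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.moderation_fit <- function(object, trait = NULL, n_points = 50L,
                                    ...) {
  if (is.null(trait)) trait <- object$spec$traits_terms[1L]
  rng <- object$trait_ranges[[trait]]
  at <- list(seq(rng[1L], rng[2L], length.out = n_points))
  names(at) <- trait
  mm <- marginal_means(object, at = at)
  ylab <- if (object$spec$dependent == "drink_indicator") {
    "P(drinking)"
  } else {
    "alcohol (g/day)"
  }
  ggplot2::ggplot(mm, ggplot2::aes(x = .data[[trait]], y = .data$response,
                                   colour = .data$intention,
                                   fill = .data$intention)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = trait, y = ylab, colour = "intention",
                  fill = "intention") +
    ggplot2::theme_minimal()
}

#' Influence and residual diagnostics for a moderation fit
#'
#' Residual quantile-quantile data and subject-level leverage (random-effect
#' magnitudes and per-subject mean residuals), as a light-weight robustness
#' report.
#'
#' @param fit A `moderation_fit` (LMM).
#' @return A list with `residuals` tibble and `subjects` tibble.
#' @export
moderation_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "moderation_fit"))
  res <- stats::residuals(fit$model)
  data <- fit$data
  subjects <- tibble::tibble(subject = data$subject, resid = res) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(mean_resid = mean(.data$resid),
                     abs_resid = mean(abs(.data$resid)),
                     n_days = dplyr::n(), .groups = "drop")
  qq <- stats::qqnorm(res, plot.it = FALSE)
  list(
    residuals = tibble::tibble(theoretical = qq$x, sample = qq$y),
    subjects = subjects
  )
}
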