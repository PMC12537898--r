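intention_levels <- c("none", "no_more", "less")

#' Configuration of the synthetic EMA cohort generator
#'
#' Defaults emulate a one-year smartphone study in alcohol use disorder:
#' 67 subjects followed for up to 359 days, a drinking-intention item every
#' 8 days (categories: no specific intention, drink no more than usual, drink
#' less than usual), and a consumption report every 2 days covering each of
#' the two past days. Daily grams of ethanol follow a hurdle process: a
#' logistic drinking indicator, then a log-normal amount on the log(g+1)
#' scale, both with subject random effects and trait-by-intention
#' interactions. Default coefficients are calibrated so that the cohort
#' reproduces the anchor statistics of such studies (about 32 g/day on
#' average, right-skewed with many abstinent days, 'drink less' active on
#' about a quarter of days, about a quarter of days lost to missingness, and
#' an intraclass correlation near 0.16 for log consumption).
#'
#' @param n_subjects Number of subjects (default 67).
#' @param horizon Study length in days (default 359).
#' @param intention_stationary Stationary probabilities of the three intention
#'   categories (`none`, `no_more`, `less`); must sum to 1.
#' @param intention_persistence Markov persistence of the 8-day intention
#'   blocks in \[0, 1\): the next block repeats the current category with this
#'   extra weight, otherwise draws from the stationary distribution (which is
#'   preserved for any value).
#' @param drink_coef Named coefficients of the logistic drinking part
#'   (logit scale): `intercept`, `no_more`, `less`, `omega`,
#'   `omega_no_more`, `omega_less`.
#' @param amount_coef Named coefficients of the conditional amount part on the
#'   log(grams + 1) scale: same names as `drink_coef` plus optional regional
#'   terms `hip`, `hip_no_more`, `hip_less`, `vs`, `vs_no_more`, `vs_less`,
#'   `vmpfc`, `vmpfc_no_more`, `vmpfc_less` (per standardised signature
#'   unit).
#' @param drink_intercept_sd SD of the subject random intercept on the logit
#'   drinking scale.
#' @param amount_intercept_sd,amount_slope_sd SDs of the subject random
#'   intercept and the two random intention slopes on the log-gram scale.
#' @param residual_sd Residual SD of the amount part (log-gram scale).
#' @param signature_cor Pairwise correlation of the three simulated regional
#'   model-based signatures (hippocampus, ventral striatum, vmPFC).
#' @param missingness Target share of study days lost because the covering
#'   rating and/or report is missing; each stream is dropped completely at
#'   random with rate `1 - sqrt(1 - missingness)`.
#' @param rating_interval,rating_window,report_interval Assessment schedule in
#'   days: intentions queried every `rating_interval` days and applied to
#'   `rating_window` days from the query day; consumption queried every
#'   `report_interval` days for the two preceding days.
#'
#' @return A list with class `ema_config`.
#' @export
ema_config <- function(n_subjects = 67L,
                       horizon = 359L,
                       intention_stationary = c(none = 0.45, no_more = 0.30,
                                                less = 0.25),
                       intention_persistence = 0.4,
                       drink_coef = c(intercept = 0.663, no_more = 0.444,
                                      less = 0.077, omega = -0.357,
                                      omega_no_more = -0.580,
                                      omega_less = -1.171),
                       amount_coef = c(intercept = 3.5, no_more = 0.29,
                                       less = 0.14, omega = -0.17,
                                       omega_no_more = -0.49,
                                       omega_less = -1.06),
                       drink_intercept_sd = 0.9,
                       amount_intercept_sd = 0.8,
                       amount_slope_sd = 0.3,
                       residual_sd = 0.8,
                       signature_cor = 0.5,
                       missingness = 0.24,
                       rating_interval = 8L,
                       rating_window = 8L,
                       report_interval = 2L) {
  stopifnot(n_subjects >= 1L, horizon >= 1L)
  if (length(intention_stationary) != 3L ||
      any(intention_stationary < 0) ||
      abs(sum(intention_stationary) - 1) > 1e-8) {
    stop("`intention_stationary` must be 3 nonnegative probabilities",
         " summing to 1.", call. = FALSE)
  }
  names(intention_stationary) <- intention_levels
  stopifnot(intention_persistence >= 0, intention_persistence < 1,
            missingness >= 0, missingness < 1,
            drink_intercept_sd >= 0, amount_intercept_sd >= 0,
            amount_slope_sd >= 0, residual_sd >= 0,
            signature_cor > -0.5, signature_cor < 1)
  structure(
    list(n_subjects = as.integer(n_subjects), horizon = as.integer(horizon),
         intention_stationary = intention_stationary,
         intention_persistence = intention_persistence,
         drink_coef = drink_coef, amount_coef = amount_coef,
         drink_intercept_sd = drink_intercept_sd,
         amount_intercept_sd = amount_intercept_sd,
         amount_slope_sd = amount_slope_sd,
         residual_sd = residual_sd,
         signature_cor = signature_cor,
         missingness = missingness,
         rating_interval = as.integer(rating_interval),
         rating_window = as.integer(rating_window),
         report_interval = as.integer(report_interval)),
    class = "ema_config"
  )
}

#' @exportS3Method base::print
print.ema_config <- function(x, ...) {
  cat("<ema_config>", x$n_subjects, "subjects,", x$horizon, "days;",
      "intention every", x$rating_interval, "days, reports every",
      x$report_interval, "days; day-level missingness",
      paste0(x$missingness, "\n"))
  invisible(x)
}

coef_or_zero <- function(coefs, name) {
  if (name %in% names(coefs)) unname(coefs[[name]]) else 0
}

# correlated standard-normal regional signatures via a Cholesky factor
draw_signatures <- function(n, rho) {
  sigma <- matrix(rho, 3L, 3L)
  diag(sigma) <- 1
  z <- matrix(rnorm(3L * n), n, 3L) %*% chol(sigma)
  colnames(z) <- c("sig_hippocampus", "sig_vs", "sig_vmpfc")
  tibble::as_tibble(z)
}

#' Simulate a synthetic EMA cohort
#'
#' Generates subject traits (model-based weight omega, correlated regional
#' model-based signatures, subject random effects), 8-day intention blocks
#' from a stationary Markov chain, daily grams from the hurdle log-normal
#' process, and assembles the raw assessment streams on their schedules:
#' intention ratings every 8 days and consumption reports every 2 days
#' covering the two preceding days each. Missingness removes whole ratings or
#' reports completely at random.
#'
#' @param config An [ema_config()].
#' @param traits Optional tibble with columns `subject` and `omega` (and
#'   optionally the three signature columns) to use instead of drawing traits;
#'   overrides `n_subjects`.
#' @return A list with class `ema_cohort`: `traits`, `ratings` (subject,
#'   query_day, category), `reports` (subject, query_day, grams_day_minus_1,
#'   grams_day_minus_2), and `daily_truth` (the complete latent daily record
#'   before missingness, for calibration checks).
#' @examples
#' set.seed(1)
#' cohort <- simulate_ema_cohort(ema_config(n_subjects = 5, horizon = 32))
#' cohort$ratings
#' @export
simulate_ema_cohort <- function(config = ema_config(), traits = NULL) {
  stopifnot(inherits(config, "ema_config"))
  if (is.null(traits)) {
    n <- config$n_subjects
    traits <- dplyr::bind_cols(
      tibble::tibble(subject = sprintf("p%03d", seq_len(n)),
                     omega = rbeta(n, 2.4, 1.4)),
      draw_signatures(n, config$signature_cor)
    )
  } else {
    stopifnot(all(c("subject", "omega") %in% names(traits)))
    traits <- tibble::as_tibble(traits)
    n <- nrow(traits)
    if (!all(c("sig_hippocampus", "sig_vs", "sig_vmpfc") %in%
               names(traits))) {
      traits <- dplyr::bind_cols(traits,
                                 draw_signatures(n, config$signature_cor))
    }
  }
  traits$u_drink0 <- rnorm(n, 0, config$drink_intercept_sd)
  traits$u_amount0 <- rnorm(n, 0, config$amount_intercept_sd)
  traits$u_less <- rnorm(n, 0, config$amount_slope_sd)
  traits$u_no_more <- rnorm(n, 0, config$amount_slope_sd)

  pi0 <- config$intention_stationary
  rho <- config$intention_persistence
  rating_days <- seq(1L, config$horizon, by = config$rating_interval)
  n_blocks <- length(rating_days)
  report_days <- seq(3L, config$horizon + 2L, by = config$report_interval)

  dc <- config$drink_coef
  ac <- config$amount_coef

  per_subject <- purrr::map(seq_len(n), function(i) {
    tr <- traits[i, ]
    # intention blocks: sticky Markov chain with stationary pi0
    cats <- character(n_blocks)
    cats[1L] <- sample(intention_levels, 1L, prob = pi0)
    if (n_blocks > 1L) {
      for (b in 2:n_blocks) {
        cats[b] <- if (runif(1) < rho) cats[b - 1L] else {
          sample(intention_levels, 1L, prob = pi0)
        }
      }
    }
    ratings <- tibble::tibble(subject = tr$subject, query_day = rating_days,
                              category = cats)
    # daily truth over the horizon (intention = covering block)
    block <- pmin(((seq_len(config$horizon) - 1L) %/%
                     config$rating_interval) + 1L, n_blocks)
    intent <- cats[block]
    is_less <- as.numeric(intent == "less")
    is_nomore <- as.numeric(intent == "no_more")
    sig_lp <- function(coefs) {
      coef_or_zero(coefs, "hip") * tr$sig_hippocampus +
        coef_or_zero(coefs, "vs") * tr$sig_vs +
        coef_or_zero(coefs, "vmpfc") * tr$sig_vmpfc +
        (coef_or_zero(coefs, "hip_less") * tr$sig_hippocampus +
           coef_or_zero(coefs, "vs_less") * tr$sig_vs +
           coef_or_zero(coefs, "vmpfc_less") * tr$sig_vmpfc) * is_less +
        (coef_or_zero(coefs, "hip_no_more") * tr$sig_hippocampus +
           coef_or_zero(coefs, "vs_no_more") * tr$sig_vs +
           coef_or_zero(coefs, "vmpfc_no_more") * tr$sig_vmpfc) * is_nomore
    }
    lp_drink <- coef_or_zero(dc, "intercept") +
      coef_or_zero(dc, "no_more") * is_nomore +
      coef_or_zero(dc, "less") * is_less +
      coef_or_zero(dc, "omega") * tr$omega +
      coef_or_zero(dc, "omega_no_more") * tr$omega * is_nomore +
      coef_or_zero(dc, "omega_less") * tr$omega * is_less +
      sig_lp(dc) + tr$u_drink0
    drink <- rbinom(config$horizon, 1L, plogis(lp_drink))
    lp_amount <- coef_or_zero(ac, "intercept") +
      coef_or_zero(ac, "no_more") * is_nomore +
      coef_or_zero(ac, "less") * is_less +
      coef_or_zero(ac, "omega") * tr$omega +
      coef_or_zero(ac, "omega_no_more") * tr$omega * is_nomore +
      coef_or_zero(ac, "omega_less") * tr$omega * is_less +
      sig_lp(ac) + tr$u_amount0 +
      tr$u_less * is_less + tr$u_no_more * is_nomore
    y <- lp_amount + rnorm(config$horizon, 0, config$residual_sd)
    grams <- drink * pmax(expm1(y), 0)
    daily_truth <- tibble::tibble(subject = tr$subject,
                                  day = seq_len(config$horizon),
                                  grams = grams, intention = intent)
    gram_at <- function(day) {
      ifelse(day >= 1L & day <= config$horizon,
             grams[pmax(pmin(day, config$horizon), 1L)], NA_real_)
    }
    reports <- tibble::tibble(
      subject = tr$subject, query_day = report_days,
      grams_day_minus_1 = gram_at(report_days - 1L),
      grams_day_minus_2 = gram_at(report_days - 2L)
    )
    list(ratings = ratings, reports = reports, daily_truth = daily_truth)
  })

  ratings <- dplyr::bind_rows(purrr::map(per_subject, "ratings"))
  reports <- dplyr::bind_rows(purrr::map(per_subject, "reports"))
  daily_truth <- dplyr::bind_rows(purrr::map(per_subject, "daily_truth"))

  m_stream <- 1 - sqrt(1 - config$missingness)
  if (m_stream > 0) {
    ratings <- ratings[runif(nrow(ratings)) >= m_stream, , drop = FALSE]
    reports <- reports[runif(nrow(reports)) >= m_stream, , drop = FALSE]
  }
  structure(list(traits = traits, ratings = ratings, reports = reports,
                 daily_truth = daily_truth, config = config),
            class = "ema_cohort")
}

#' @exportS3Method base::print
print.ema_cohort <- function(x, ...) {
  cat("<ema_cohort>", nrow(x$traits), "subjects,",
      nrow(x$ratings), "intention ratings,",
      nrow(x$reports), "consumption reports\n")
  invisible(x)
}

#' Restructure raw EMA streams into one record per day
#'
#' Each intention rating is assigned to its query day and the following
#' `window - 1` days; where coverage windows overlap, the later rating wins.
#' Each consumption report contributes grams to the two days preceding its
#' query day. Days covered by both streams are valid; all others are invalid
#' and dropped (or kept flagged with `keep_invalid = TRUE`). Conflicting
#' duplicate grams for one day raise an error listing the conflicts.
#'
#' @param ratings Tibble `subject, query_day, category`.
#' @param reports Tibble `subject, query_day, grams_day_minus_1,
#'   grams_day_minus_2`.
#' @param window Days covered by one intention rating (default 8).
#' @param keep_invalid Keep rows for days lacking one stream, flagged
#'   `valid = FALSE`.
#' @return A tibble `subject, day, grams, intention, valid`.
#' @examples
#' ratings <- tibble::tibble(subject = "a", query_day = 1, category = "less")
#' reports <- tibble::tibble(subject = "a", query_day = c(3, 5, 7, 9),
#'                           grams_day_minus_1 = 10, grams_day_minus_2 = 0)
#' restructure_ema(ratings, reports)
#' @export
restructure_ema <- function(ratings, reports, window = 8L,
                            keep_invalid = FALSE) {
  stopifnot(all(c("subject", "query_day", "category") %in% names(ratings)),
            all(c("subject", "query_day", "grams_day_minus_1",
                  "grams_day_minus_2") %in% names(reports)))
  if (nrow(ratings) > 0L && !all(ratings$category %in% intention_levels)) {
    stop("Unknown intention category; expected one of: ",
         paste(intention_levels, collapse = ", "), call. = FALSE)
  }
  # later ratings overwrite earlier ones on overlapping days: expand windows,
  # then keep the row from the latest query per subject-day
  intent_daily <- ratings |>
    dplyr::arrange(.data$subject, .data$query_day) |>
    dplyr::mutate(.rating_order = dplyr::row_number()) |>
    tidyr::crossing(offset = seq_len(window) - 1L) |>
    dplyr::mutate(day = .data$query_day + .data$offset) |>
    dplyr::arrange(dplyr::desc(.data$.rating_order)) |>
    dplyr::distinct(.data$subject, .data$day, .keep_all = TRUE) |>
    dplyr::select("subject", "day", intention = "category")

  grams_daily <- dplyr::bind_rows(
    dplyr::transmute(reports, .data$subject, day = .data$query_day - 1L,
                     grams = .data$grams_day_minus_1),
    dplyr::transmute(reports, .data$subject, day = .data$query_day - 2L,
                     grams = .data$grams_day_minus_2)
  ) |>
    dplyr::filter(.data$day >= 1L, !is.na(.data$grams)) |>
    dplyr::arrange(.data$subject, .data$day, .data$grams)

  dup <- duplicated(grams_daily[c("subject", "day")])
  if (any(dup)) {
    # duplicates are sorted adjacently; a conflict is a duplicate whose grams
    # differ from the preceding row for the same day
    prev_same <- dup & c(FALSE, abs(diff(grams_daily$grams)) > 1e-12)
    if (any(prev_same)) {
      offenders <- unique(paste0(grams_daily$subject[prev_same], "/day ",
                                 grams_daily$day[prev_same]))
      stop("Conflicting grams reported for the same day: ",
           paste(offenders, collapse = ", "), call. = FALSE)
    }
    grams_daily <- grams_daily[!dup, , drop = FALSE]
  }

  daily <- dplyr::full_join(grams_daily, intent_daily,
                            by = c("subject", "day")) |>
    dplyr::mutate(valid = !is.na(.data$grams) & !is.na(.data$intention)) |>
    dplyr::arrange(.data$subject, .data$day)
  if (!keep_invalid) {
    daily <- dplyr::filter(daily, .data$valid)
  }
  daily[c("subject", "day", "grams", "intention", "valid")]
}

#' Descriptive summary of a daily EMA record
#'
#' @param daily Tibble from [restructure_ema()] (valid days are used).
#' @param traits Optional traits tibble; when given, Spearman correlations
#'   between each trait column (e.g. `omega`, `mb_score`) and the subject's
#'   share of 'drink less' days are reported.
#' @return A list of class `ema_summary`: `cohort` (one-row tibble of
#'   cohort-level statistics), `per_subject`, and `trait_correlations` (or
#'   `NULL`).
#' @export
summarize_ema <- function(daily, traits = NULL) {
  stopifnot(all(c("subject", "day", "grams", "intention") %in% names(daily)))
  if ("valid" %in% names(daily)) daily <- daily[daily$valid, , drop = FALSE]
  if (nrow(daily) == 0L) {
    stop("No valid days to summarise.", call. = FALSE)
  }
  per_subject <- daily |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      valid_days = dplyr::n(),
      mean_grams = mean(.data$grams),
      pct_less = mean(.data$intention == "less"),
      pct_abstinent = mean(.data$grams == 0),
      .groups = "drop"
    )
  cohort <- tibble::tibble(
    n_subjects = nrow(per_subject),
    valid_days_mean = mean(per_subject$valid_days),
    valid_days_sd = sd(per_subject$valid_days),
    grams_mean = mean(daily$grams),
    grams_sd = sd(daily$grams),
    pct_abstinent = mean(daily$grams == 0),
    pct_none = mean(daily$intention == "none"),
    pct_no_more = mean(daily$intention == "no_more"),
    pct_less = mean(daily$intention == "less")
  )
  trait_correlations <- NULL
  if (!is.null(traits)) {
    trait_cols <- intersect(
      c("omega", "mb_score", "sig_hippocampus", "sig_vs", "sig_vmpfc"),
      names(traits)
    )
    joined <- dplyr::inner_join(per_subject, traits, by = "subject")
    trait_correlations <- purrr::map(trait_cols, function(col) {
      ct <- suppressWarnings(
        stats::cor.test(joined[[col]], joined$pct_less, method = "spearman")
      )
      tibble::tibble(trait = col, spearman_rho = unname(ct$estimate),
                     p = ct$p.value)
    }) |> dplyr::bind_rows()
  }
  structure(list(cohort = cohort, per_subject = per_subject,
                 trait_correlations = trait_correlations),
            class = "ema_summary")
}

#' @exportS3Method base::print
print.ema_summary <- function(x, ...) {
  cat("<ema_summary>\n")
  print(x$cohort)
  if (!is.null(x$trait_correlations)) {
    cat("Spearman correlations with %% 'drink less' days:\n")
    print(x$trait_correlations)
  }
  invisible(x)
}

#' Plot daily consumption trajectories coloured by active intention
#'
#' @param daily Tibble from [restructure_ema()].
#' @param subjects Optional subject ids to display (default: first 4).
#' @return A ggplot object.
#' @export
plot_drinking_trajectory <- function(daily, subjects = NULL) {
  if ("valid" %in% names(daily)) daily <- daily[daily$valid, , drop = FALSE]
  if (is.null(subjects)) subjects <- head(unique(daily$subject), 4L)
  df <- daily[daily$subject %in% subjects, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$grams,
                                   colour = .data$intention)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~subject, ncol = 1L) +
    ggplot2::labs(x = "study day", y = "alcohol (g/day)",
                  colour = "intention") +
    ggplot2::theme_minimal()
}
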