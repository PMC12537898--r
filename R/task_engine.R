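#' Configuration of the two-step task environment
#'
#' The task has one first-stage state with two actions, each leading to one of
#' two second-stage states with probability `p_common` (the "common"
#' transition) or to the other state ("rare"). Each second-stage action pays a
#' nonzero integer number of points drifting over trials according to a
#' Gaussian random walk reflected at the payoff bounds.
#'
#' @param n_trials Number of trials (default 201).
#' @param p_common Probability of the common transition, in (0.5, 1].
#' @param walk_sd Standard deviation of the Gaussian payoff-walk increments,
#'   in points per trial.
#' @param payoff_min,payoff_max Integer payoff bounds; payoffs are drawn from
#'   `{payoff_min, ..., -1, 1, ..., payoff_max}` (zero is never delivered).
#'
#' @return A list with class `task_config`.
#' @examples
#' task_config(n_trials = 50)
#' @export
task_config <- function(n_trials = 201L, p_common = 0.7, walk_sd = 2,
                        payoff_min = -5L, payoff_max = 5L) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) {
    stop("`n_trials` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(p_common) || length(p_common) != 1L || is.na(p_common) ||
      p_common <= 0.5 || p_common > 1) {
    stop("`p_common` must be a single probability in (0.5, 1].", call. = FALSE)
  }
  if (!is.numeric(walk_sd) || length(walk_sd) != 1L || !is.finite(walk_sd) ||
      walk_sd < 0) {
    stop("`walk_sd` must be a single finite nonnegative number.", call. = FALSE)
  }
  payoff_min <- as.integer(payoff_min)
  payoff_max <- as.integer(payoff_max)
  if (!(payoff_min < 0L && 0L < payoff_max)) {
    stop("Payoff bounds must satisfy payoff_min < 0 < payoff_max.",
         call. = FALSE)
  }
  structure(
    list(n_trials = n_trials, p_common = p_common, walk_sd = walk_sd,
         payoff_min = payoff_min, payoff_max = payoff_max),
    class = "task_config"
  )
}

#' @exportS3Method base::print
print.task_config <- function(x, ...) {
  cat("<task_config> two-step task:",
      x$n_trials, "trials, p(common) =", x$p_common,
      ", payoffs", x$payoff_min, "..", x$payoff_max,
      "(walk sd", paste0(x$walk_sd, ")\n"))
  invisible(x)
}

# common second-stage state for each first-stage action: action k -> state k
common_state <- function(a1) a1

# round a latent walk value to the nearest allowed nonzero integer payoff;
# latents in (-0.5, 0.5) round away from zero toward their sign, exact zeros
# are resolved by a fair coin (the payoff set excludes zero)
round_payoff <- function(latent, payoff_min, payoff_max) {
  v <- round(latent)
  zero <- v == 0
  if (any(zero)) {
    s <- sign(latent[zero])
    coin <- sample(c(-1, 1), sum(s == 0), replace = TRUE)
    s[s == 0] <- coin
    v[zero] <- s
  }
  pmin(pmax(v, payoff_min), payoff_max)
}

#' Generate drifting second-stage payoffs
#'
#' Latent payoff values evolve as Gaussian random walks with increments of
#' standard deviation `walk_sd`, reflected at `[payoff_min, payoff_max]`. The
#' delivered payoff on each trial is the latent value rounded to the nearest
#' allowed nonzero integer.
#'
#' @param config A [task_config()].
#' @param start Optional 2 x 2 matrix (state x action) of starting latent
#'   values; by default drawn uniformly over the payoff range.
#'
#' @return A list of class `payoff_walks` with elements `values` and `latent`,
#'   each an `n_trials x 2 x 2` array indexed `[trial, state, action]`.
#' @examples
#' set.seed(1)
#' w <- generate_payoff_walks(task_config(n_trials = 10))
#' w$values[1, , ]
#' @export
generate_payoff_walks <- function(config = task_config(), start = NULL) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_trials
  lo <- config$payoff_min
  hi <- config$payoff_max
  latent <- array(NA_real_, dim = c(n, 2L, 2L))
  values <- array(NA_real_, dim = c(n, 2L, 2L))
  if (is.null(start)) {
    start <- matrix(runif(4L, lo, hi), 2L, 2L)
  }
  stopifnot(is.matrix(start), all(dim(start) == 2L),
            all(start >= lo & start <= hi))
  for (s in 1:2) {
    for (a in 1:2) {
      x <- numeric(n)
      x[1L] <- start[s, a]
      if (n > 1L) {
        inc <- rnorm(n - 1L, 0, config$walk_sd)
        for (t in 2:n) x[t] <- reflect(x[t - 1L] + inc[t - 1L], lo, hi)
      }
      latent[, s, a] <- x
      values[, s, a] <- round_payoff(x, lo, hi)
    }
  }
  structure(list(values = values, latent = latent, config = config),
            class = "payoff_walks")
}

# reflect a scalar into [lo, hi] (repeatedly, for large excursions)
reflect <- function(x, lo, hi) {
  width <- hi - lo
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' Sample second-stage states for first-stage actions
#'
#' Each first-stage action has its own common second-stage state (action 0 ->
#' state 0, action 1 -> state 1), reached with probability `p_common`;
#' otherwise the rare state is entered.
#'
#' @param a1 Integer vector of first-stage actions (0 or 1).
#' @param config A [task_config()].
#'
#' @return A tibble with columns `a1`, `s2`, `transition`
#'   (`"common"`/`"rare"`).
#' @examples
#' set.seed(1)
#' sample_transition(c(0L, 1L, 0L), task_config())
#' @export
sample_transition <- function(a1, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  if (!all(a1 %in% c(0L, 1L))) {
    stop("`a1` must contain only 0/1 actions.", call. = FALSE)
  }
  a1 <- as.integer(a1)
  is_common <- runif(length(a1)) < config$p_common
  s2 <- ifelse(is_common, common_state(a1), 1L - common_state(a1))
  tibble::tibble(
    a1 = a1, s2 = as.integer(s2),
    transition = ifelse(is_common, "common", "rare")
  )
}

trial_columns <- c("subject", "trial", "a1", "transition", "s2", "a2", "points")

validate_trials <- function(trials, call_label = "trials") {
  if (!is.data.frame(trials)) {
    stop(call_label, " must be a data frame.", call. = FALSE)
  }
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0L) {
    stop(call_label, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_code <- function(col, ok) {
    bad <- which(!(trials[[col]] %in% ok))
    if (length(bad) > 0L) {
      stop(call_label, ": column `", col, "` has out-of-range value ",
           trials[[col]][bad[1L]], " at row ", bad[1L], ".", call. = FALSE)
    }
  }
  bad_code("a1", c(0L, 1L))
  bad_code("a2", c(0L, 1L))
  bad_code("s2", c(0L, 1L))
  bad_code("transition", c("common", "rare"))
  if (any(trials$points == 0)) {
    stop(call_label, ": `points` must be nonzero (first offending row ",
         which(trials$points == 0)[1L], ").", call. = FALSE)
  }
  expected <- ifelse(trials$s2 == common_state(trials$a1), "common", "rare")
  bad <- which(expected != trials$transition)
  if (length(bad) > 0L) {
    stop(call_label, ": `transition` label inconsistent with (a1, s2) mapping",
         " at row ", bad[1L], " (expected '", expected[bad[1L]], "').",
         call. = FALSE)
  }
  invisible(trials)
}

#' Write and read trial-level two-step records
#'
#' The trials CSV has columns `subject, trial, a1, transition, s2, a2, points`
#' with 1-based trial indices, 0/1 action and state codes, and nonzero integer
#' points. Reading validates the schema strictly, including consistency of the
#' `transition` label with the action-to-state mapping.
#'
#' @param trials A trials tibble.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a validated tibble.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials[trial_columns], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject = readr::col_character(),
      trial = readr::col_integer(),
      a1 = readr::col_integer(),
      transition = readr::col_character(),
      s2 = readr::col_integer(),
      a2 = readr::col_integer(),
      points = readr::col_double()
    )
  )
  validate_trials(trials, call_label = paste0("trials file '", path, "'"))
  tibble::as_tibble(trials)
}
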