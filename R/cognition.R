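# Cleaning of trial-level cognitive task logs (XNA1: 17 trials, exogenous
# attending; XNA2: 27 trials, endogenous attending + updating) into
# per-session outcomes.

#' Reaction-time validity filter
#'
#' Removes trials whose reaction time is shorter than `rt_min` or longer than
#' `rt_max`; the bounds themselves survive (removal is strict).
#'
#' @param trials data frame with an `rt_ms` column.
#' @param rt_min,rt_max validity bounds in ms (defaults 125 and 5000).
#' @return the retained trials (possibly zero rows).
#' @export
filter_rt_validity <- function(trials, rt_min = 125, rt_max = 5000) {
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)
  trials[trials$rt_ms >= rt_min & trials$rt_ms <= rt_max, , drop = FALSE]
}

#' Summarise trial-level logs into per-session outcomes
#'
#' For every (participant, task, session) combination: the error count is the
#' number of incorrect responses, counted before any reaction-time filtering
#' (errors are response-based, not latency-based); the mean reaction time is
#' taken over correct trials surviving the validity filter; the caffeine flag
#' is yes iff the reported prior-hour dose is at least `caffeine_threshold_mg`
#' (the one-espresso rule, 200 mg); time of day is fractional hours since
#' local midnight.
#'
#' Sessions with no surviving correct trial get a missing mean reaction time
#' and a warning.
#'
#' @param trials data frame with columns `participant_id`, `task`,
#'   `session_timestamp`, `trial_index`, `rt_ms`, `correct`, `caffeine_mg`.
#' @param caffeine_threshold_mg binarisation threshold (default 200).
#' @param rt_min,rt_max validity bounds passed to [filter_rt_validity()].
#' @return tibble, one row per session x task: `participant_id`, `task`,
#'   `session_timestamp`, `time_of_day_h`, `mean_rt_ms`, `n_errors`,
#'   `n_valid_rt`, `caffeine_flag`.
#' @export
summarize_sessions <- function(trials, caffeine_threshold_mg = 200,
                               rt_min = 125, rt_max = 5000) {
  stopifnot(all(c(
    "participant_id", "task", "session_timestamp", "rt_ms", "correct",
    "caffeine_mg"
  ) %in% names(trials)))
  out <- trials |>
    dplyr::group_by(.data$participant_id, .data$task, .data$session_timestamp) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_errors = sum(!.data$correct),
      n_valid_rt = sum(.data$correct & .data$rt_ms >= rt_min & .data$rt_ms <= rt_max),
      mean_rt_ms = mean(.data$rt_ms[.data$correct & .data$rt_ms >= rt_min &
        .data$rt_ms <= rt_max]),
      caffeine_mg = .data$caffeine_mg[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_rt_ms = ifelse(is.nan(.data$mean_rt_ms), NA_real_, .data$mean_rt_ms),
      caffeine_flag = .data$caffeine_mg >= caffeine_threshold_mg,
      time_of_day_h = hours_since_midnight(.data$session_timestamp)
    )
  n_empty <- sum(is.na(out$mean_rt_ms))
  if (n_empty > 0L) {
    warning(sprintf(
      "%d session(s) with no surviving correct trial: mean RT set to NA", n_empty
    ), call. = FALSE)
  }
  out
}

#' Flag low-engagement sessions for exclusion
#'
#' Sessions with at least `xna1_threshold` errors on XNA1 or at least
#' `xna2_threshold` errors on XNA2 are flagged as low engagement (the
#' participant is assumed not to have engaged with the task). The operation is
#' idempotent and only ever adds the `excluded`/`reason` columns.
#'
#' @param summaries output of [summarize_sessions()].
#' @param xna1_threshold,xna2_threshold minimum error counts triggering
#'   exclusion (defaults 8 and 10).
#' @return `summaries` with logical `excluded` and character `reason` columns.
#' @export
exclude_low_engagement <- function(summaries, xna1_threshold = 8,
                                   xna2_threshold = 10) {
  bad <- (summaries$task == "XNA1" & summaries$n_errors >= xna1_threshold) |
    (summaries$task == "XNA2" & summaries$n_errors >= xna2_threshold)
  summaries$excluded <- bad
  summaries$reason <- ifelse(bad, "low engagement", "")
  summaries
}

#' Shapiro-Wilk gated Box-Cox transform
#'
#' Tests normality with a Shapiro-Wilk test; when `p < alpha`, estimates the
#' Box-Cox exponent by profile maximum likelihood over a grid of lambda values
#' (`[-5, 5]` in steps of 0.01) and returns the transformed data, otherwise
#' returns the data untouched (identity, lambda = 1 by convention). The
#' transform is strictly increasing for every lambda, so ranks are preserved.
#' For n > 5000 the Shapiro-Wilk statistic is computed on a deterministic
#' evenly spaced thinning of the sample (the test is defined for n <= 5000).
#'
#' @param values numeric outcome values; must be positive after `shift`.
#' @param alpha significance level of the normality gate (default 0.05).
#' @param shift additive offset applied before transforming (default 0); use
#'   it when values are not strictly positive.
#' @param lambda_grid candidate exponents for the profile likelihood.
#' @return object of class `boxcox_transform`: list with `lambda`, `shift`,
#'   `applied`, `shapiro_p`, `transformed`, and `transform` (a function).
#' @export
boxcox_if_needed <- function(values, alpha = 0.05, shift = 0,
                             lambda_grid = seq(-5, 5, by = 0.01)) {
  x <- values + shift
  n <- length(x)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  if (any(x <= 0)) {
    stop("values must be positive; supply a `shift` making them so", call. = FALSE)
  }
  x_sw <- if (n > 5000L) x[round(seq(1L, n, length.out = 5000L))] else x
  sw <- stats::shapiro.test(x_sw)
  bc_fun <- function(lambda, shift) {
    force(lambda); force(shift)
    function(y) {
      z <- y + shift
      if (abs(lambda) < 1e-12) log(z) else (z^lambda - 1) / lambda
    }
  }
  if (sw$p.value >= alpha) {
    out <- list(
      lambda = 1, shift = shift, applied = FALSE, shapiro_p = sw$p.value,
      transformed = values, transform = identity
    )
    return(structure(out, class = "boxcox_transform"))
  }
  logx <- log(x)
  s <- sum(logx)
  ll <- vapply(lambda_grid, function(l) {
    y <- if (abs(l) < 1e-12) logx else (x^l - 1) / l
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * s
  }, numeric(1))
  lambda <- lambda_grid[which.max(ll)]
  f <- bc_fun(lambda, shift)
  out <- list(
    lambda = lambda, shift = shift, applied = TRUE, shapiro_p = sw$p.value,
    transformed = f(values), transform = f
  )
  structure(out, class = "boxcox_transform")
}

#' @export
print.boxcox_transform <- function(x, ...) {
  cat(sprintf(
    "<boxcox_transform> %s (Shapiro-Wilk p = %.3g, lambda = %.2f, shift = %g)\n",
    if (x$applied) "applied" else "identity (sample passed normality gate)",
    x$shapiro_p, x$lambda, x$shift
  ))
  invisible(x)
}
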