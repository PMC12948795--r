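# Inference layer: analysis-table assembly, between-group one-way ANOVA with
# Bonferroni post-hocs and partial eta squared, random-intercept linear mixed
# models with a chronotype-by-time-of-day interaction, and the simulation
# experiments (parameter recovery, type-I error) that validate the model.

#' Assemble the modelling table
#'
#' Inner-joins the per-session cognitive summaries with chronotype
#' assignments, demographics and activity features, computes the prior-hour
#' activity covariate at every session timestamp from the epoch series, drops
#' sessions from wear-time-excluded participants, low-engagement-excluded
#' sessions and rows with missing outcome or covariates (listwise, with
#' logged counts), and pivots the two outcomes (`rt`, `errors`) into long
#' format: one row per retained session x task x outcome.
#'
#' @param features per-participant activity features with at least
#'   `participant_id` and logical `included` (see [activity_summary()]).
#' @param assignments output of [assign_quintiles()].
#' @param summaries output of [exclude_low_engagement()].
#' @param demographics data frame with `participant_id`, `age`, `sex`.
#' @param series named list of [epoch_series()] keyed by participant.
#' @param drop_excluded_sessions drop low-engagement sessions from both
#'   outcomes (default TRUE).
#' @param window_minutes prior-activity window (default 60).
#' @return tibble of analysis rows with attribute `drop_log` (named counts of
#'   rows dropped per reason).
#' @export
assemble_analysis_table <- function(features, assignments, summaries,
                                    demographics, series,
                                    drop_excluded_sessions = TRUE,
                                    window_minutes = 60) {
  orphans <- setdiff(summaries$participant_id, assignments$participant_id)
  if (length(orphans) > 0L) {
    stop(
      "participants present in session summaries but missing from ",
      "chronotype assignments: ", paste(orphans, collapse = ", "),
      call. = FALSE
    )
  }
  drop_log <- c()
  note <- function(reason, n) {
    drop_log[[reason]] <<- (drop_log[[reason]] %||% 0L) + n
    if (n > 0L) message(sprintf("dropped %d row(s): %s", n, reason))
  }

  included_ids <- features$participant_id[features$included]
  tab <- summaries
  n0 <- nrow(tab)
  tab <- tab[tab$participant_id %in% included_ids, , drop = FALSE]
  note("participant excluded by wear-time screen", n0 - nrow(tab))
  if (drop_excluded_sessions && "excluded" %in% names(tab)) {
    n0 <- nrow(tab)
    tab <- tab[!tab$excluded, , drop = FALSE]
    note("session excluded for low engagement", n0 - nrow(tab))
  }
  tab <- tab |>
    dplyr::inner_join(
      assignments[, c("participant_id", "cmq_score", "chronotype_group")],
      by = "participant_id"
    ) |>
    dplyr::inner_join(
      demographics[, c("participant_id", "age", "sex")],
      by = "participant_id"
    )

  sess <- dplyr::distinct(tab, .data$participant_id, .data$session_timestamp)
  sess$activity_prior_60min <- vapply(seq_len(nrow(sess)), function(r) {
    s <- series[[sess$participant_id[r]]]
    if (is.null(s)) return(NA_real_)
    activity_prior_window(s, sess$session_timestamp[r], window_minutes)
  }, numeric(1))
  tab <- dplyr::left_join(tab, sess,
    by = c("participant_id", "session_timestamp")
  )

  long <- tab |>
    dplyr::mutate(rt = .data$mean_rt_ms, errors = as.numeric(.data$n_errors)) |>
    tidyr::pivot_longer(
      cols = c("rt", "errors"),
      names_to = "outcome_name", values_to = "outcome_value"
    ) |>
    dplyr::select(
      "participant_id", "task", "session_timestamp", "time_of_day_h",
      "outcome_name", "outcome_value", chronotype_score = "cmq_score",
      "chronotype_group", "age", "sex", "caffeine_flag",
      "activity_prior_60min"
    )
  n0 <- nrow(long)
  long <- long[!is.na(long$outcome_value), , drop = FALSE]
  note("missing outcome (no surviving correct trial)", n0 - nrow(long))
  covars <- c(
    "time_of_day_h", "chronotype_score", "age", "sex", "caffeine_flag",
    "activity_prior_60min"
  )
  n0 <- nrow(long)
  long <- long[stats::complete.cases(long[, covars]), , drop = FALSE]
  note("missing covariate", n0 - nrow(long))
  long$sex <- factor(long$sex, levels = c("female", "male"))
  attr(long, "drop_log") <- drop_log
  long
}

#' One-way ANOVA with Bonferroni post-hocs and partial eta squared
#'
#' Classical fixed-effects one-way ANOVA on the supplied groups, partial eta
#' squared from the sums-of-squares decomposition
#' (`SS_between / (SS_between + SS_within)`), and all pairwise comparisons by
#' pooled-variance t-tests with Bonferroni correction (raw p times the number
#' of comparisons, capped at 1).
#'
#' @param values_by_group named list of numeric vectors, one per group (each
#'   with at least 2 values), or a data frame with columns `value`, `group`.
#' @return object of class `anova_result`: list with `F`, `df_between`,
#'   `df_within`, `p`, `partial_eta_sq`, and a `pairwise` tibble
#'   (`group_i`, `group_j`, `raw_p`, `bonferroni_p`).
#' @export
oneway_anova_posthoc <- function(values_by_group) {
  if (is.data.frame(values_by_group)) {
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  k <- length(values_by_group)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  gnames <- names(values_by_group) %||% as.character(seq_len(k))
  values <- unlist(values_by_group, use.names = FALSE)
  group <- factor(rep(gnames, sizes), levels = gnames)
  fit <- stats::aov(values ~ group)
  ss <- summary(fit)[[1]]
  ssb <- ss[["Sum Sq"]][1]
  ssw <- ss[["Sum Sq"]][2]
  f_stat <- ss[["F value"]][1]
  p <- ss[["Pr(>F)"]][1]
  n_comp <- k * (k - 1) / 2
  raw <- stats::pairwise.t.test(values, group,
    p.adjust.method = "none", pool.sd = TRUE
  )$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  pairwise <- tibble::tibble(
    group_i = colnames(raw)[pairs[, "col"]],
    group_j = rownames(raw)[pairs[, "row"]],
    raw_p = raw[pairs],
    bonferroni_p = pmin(1, raw[pairs] * n_comp)
  )
  structure(list(
    F = f_stat,
    df_between = k - 1,
    df_within = length(values) - k,
    p = p,
    partial_eta_sq = ssb / (ssb + ssw),
    pairwise = pairwise
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
    x$df_between, x$df_within, x$F, x$p, x$partial_eta_sq
  ))
  print(x$pairwise)
  invisible(x)
}

lmm_formula <- function() {
  outcome_value ~ time_of_day_h * chronotype_score + age + sex +
    caffeine_flag + activity_prior_60min
}

#' Fit the random-intercept linear mixed model
#'
#' REML fit of
#' `outcome ~ time_of_day * chronotype + age + sex + caffeine +
#' activity_prior_60min + (1 | participant)`
#' with Wald normal-theory 95% confidence intervals and p-values per fixed
#' effect (so an interval excluding 0 always coincides with p < 0.05). The
#' outcome may first be passed through the Shapiro-Wilk-gated Box-Cox
#' transform (`transform = "auto"`). With fewer than two participants the
#' random intercept is unidentifiable and the model degrades to OLS with a
#' warning.
#'
#' @param rows analysis table from [assemble_analysis_table()].
#' @param outcome `"rt"` or `"errors"`.
#' @param task optional task filter (`"XNA1"` or `"XNA2"`).
#' @param transform `"identity"` (default) or `"auto"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return object of class `lmm_result`: list with a `terms` tibble
#'   (`term`, `estimate`, `se`, `ll`, `ul`, `t`, `p`), variance components
#'   `var_intercept`/`var_residual`, `n_obs`, `n_participants`, `singular`,
#'   `transform`, and the underlying `fit`.
#' @export
fit_lmm <- function(rows, outcome = c("rt", "errors"), task = NULL,
                    transform = c("identity", "auto"), conf_level = 0.95) {
  outcome <- match.arg(outcome)
  transform <- match.arg(transform)
  d <- rows[rows$outcome_name == outcome, , drop = FALSE]
  if (!is.null(task)) d <- d[d$task == task, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for the requested outcome/task", call. = FALSE)
  d <- as.data.frame(d)

  trans <- NULL
  if (transform == "auto") {
    shift <- if (min(d$outcome_value) <= 0) 1 - min(d$outcome_value) else 0
    trans <- boxcox_if_needed(d$outcome_value, shift = shift)
    d$outcome_value <- trans$transformed
  }

  X <- stats::model.matrix(lmm_formula(), data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(
      "collinear design: ", paste(aliased, collapse = ", "),
      call. = FALSE
    )
  }

  n_part <- length(unique(d$participant_id))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (n_part < 2L) {
    warning("fewer than 2 participants: random intercept dropped, fitting OLS",
      call. = FALSE
    )
    fit <- stats::lm(lmm_formula(), data = d)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    var_int <- 0
    var_res <- summary(fit)$sigma^2
    singular <- TRUE
  } else {
    fml <- stats::update(lmm_formula(), . ~ . + (1 | participant_id))
    fit <- lme4::lmer(fml,
      data = d, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE)
    )
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_int <- vc$vcov[vc$grp == "participant_id"]
    var_res <- vc$vcov[vc$grp == "Residual"]
    singular <- lme4::isSingular(fit)
    if (singular) {
      warning("singular fit: random-intercept variance estimated at 0",
        call. = FALSE
      )
    }
  }
  tstat <- est / se
  terms <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ll = unname(est - z * se),
    ul = unname(est + z * se),
    t = unname(tstat),
    p = unname(2 * stats::pnorm(-abs(tstat)))
  )
  structure(list(
    terms = terms,
    var_intercept = var_int,
    var_residual = var_res,
    n_obs = nrow(d),
    n_participants = n_part,
    singular = singular,
    outcome = outcome,
    task = task,
    transform = trans,
    fit = fit
  ), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf(
    "Random-intercept LMM (%s%s): %d obs, %d participants%s\n",
    x$outcome, if (is.null(x$task)) "" else paste0(", ", x$task),
    x$n_obs, x$n_participants, if (x$singular) " [singular]" else ""
  ))
  print(as.data.frame(x$terms), digits = 4)
  cat(sprintf(
    "Random intercept var = %.2f, residual var = %.2f\n",
    x$var_intercept, x$var_residual
  ))
  invisible(x)
}

# one simulate -> clean -> assemble -> fit pass; shared by the recovery and
# type-I experiments and by run_pipeline()
simulate_and_fit <- function(config, outcome = "rt", task = "XNA1",
                             transform = "identity") {
  study <- simulate_study(config)
  scores <- score_cmq_cohort(study$cohort)
  assignments <- assign_quintiles(scores)
  feats <- dplyr::bind_rows(lapply(study$series, function(s) {
    wf <- compute_wear_fraction(s)
    tibble::tibble(
      participant_id = es_participant(s),
      wear_fraction = wf, included = wf >= 0.9
    )
  }))
  summaries <- suppressWarnings(summarize_sessions(
    study$trials,
    caffeine_threshold_mg = config$caffeine_threshold_mg
  )) |>
    exclude_low_engagement()
  tab <- suppressMessages(assemble_analysis_table(
    feats, assignments, summaries, study$cohort, study$series
  ))
  fit_lmm(tab, outcome = outcome, task = task, transform = transform)
}

# map generative config coefficients onto fitted model term names
truths_from_config <- function(config, task = "XNA1") {
  c(
    "(Intercept)" = config$beta_intercept +
      if (task == "XNA2") config$beta_task_xna2 else 0,
    "time_of_day_h" = config$beta_time,
    "chronotype_score" = config$beta_chronotype,
    "age" = config$beta_age,
    "sexmale" = config$beta_sex,
    "caffeine_flagTRUE" = config$beta_caffeine,
    "activity_prior_60min" = config$beta_activity,
    "time_of_day_h:chronotype_score" = config$beta_interaction
  )
}

#' Parameter-recovery / type-I-error experiment
#'
#' Repeatedly simulates a study under `config`, runs the full cleaning and
#' assembly pipeline, fits the mixed model, and summarises per coefficient:
#' truth, mean estimate, bias, empirical SD, Wald-CI coverage of the truth,
#' and rejection rate at alpha = 0.05. With all slope truths at zero this
#' measures the type-I error of each test. Replicates that fail to fit are
#' recorded and skipped.
#'
#' @param config a [simulation_config()]; its beta coefficients are the truth.
#' @param n_replicates number of simulated studies.
#' @param seed experiment seed; replicate r uses seed + r.
#' @param outcome,task which model to fit (defaults `"rt"`, `"XNA1"`).
#' @return object of class `recovery_report`: tibble with one row per
#'   coefficient plus attributes `n_replicates`, `n_failed`, `seed`.
#' @export
recovery_experiment <- function(config, n_replicates = 200, seed = 1,
                                outcome = "rt", task = "XNA1") {
  if (n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  truths <- truths_from_config(config, task)
  est <- ll <- ul <- p <- matrix(
    NA_real_, n_replicates, length(truths),
    dimnames = list(NULL, names(truths))
  )
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$rng_seed <- as.integer((as.double(seed) + r) %% 2147483647)
    res <- tryCatch(
      suppressWarnings(simulate_and_fit(cfg, outcome, task)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    m <- match(names(truths), res$terms$term)
    est[r, ] <- res$terms$estimate[m]
    ll[r, ] <- res$terms$ll[m]
    ul[r, ] <- res$terms$ul[m]
    p[r, ] <- res$terms$p[m]
  }
  ok <- stats::complete.cases(est)
  report <- tibble::tibble(
    term = names(truths),
    truth = unname(truths),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(truths),
    empirical_sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
    coverage = vapply(seq_along(truths), function(j) {
      mean(ll[ok, j] <= truths[j] & truths[j] <= ul[ok, j])
    }, numeric(1)),
    rejection_rate = colMeans(p[ok, , drop = FALSE] < 0.05)
  )
  structure(report,
    class = c("recovery_report", class(report)),
    n_replicates = sum(ok), n_failed = n_failed, seed = seed,
    outcome = outcome, task = task,
    estimates = est[ok, , drop = FALSE]
  )
}

#' Required sample size for the between-groups test of a repeated-measures ANOVA
#'
#' Smallest total N such that the between-groups F test (df `k - 1`, `N - k`)
#' with noncentrality `N * m * f^2 / (1 + (m - 1) * rho)` reaches the target
#' power. Every assumption (alpha, power, repeated-measures correlation) is an
#' explicit argument because such calculations are meaningless without them.
#'
#' @param effect_f Cohen's f effect size (> 0).
#' @param n_groups number of groups `k`.
#' @param n_measurements repeated measurements per participant `m`.
#' @param alpha significance level (default 0.05).
#' @param power target power in (0, 1) (default 0.8).
#' @param corr_rm assumed correlation among repeated measures in `[0, 1)`.
#' @param max_n search ceiling.
#' @return smallest total sample size (count).
#' @export
required_sample_anova_rm <- function(effect_f, n_groups, n_measurements,
                                     alpha = 0.05, power = 0.8, corr_rm = 0.5,
                                     max_n = 1e6) {
  stopifnot(effect_f > 0, power > 0, power < 1, corr_rm >= 0, corr_rm < 1)
  k <- n_groups
  for (n in seq(2 * k, max_n)) {
    lambda <- n * n_measurements * effect_f^2 / (1 + (n_measurements - 1) * corr_rm)
    crit <- stats::qf(1 - alpha, k - 1, n - k)
    pw <- 1 - stats::pf(crit, k - 1, n - k, ncp = lambda)
    if (pw >= power) return(n)
  }
  stop("target power unreachable below max_n", call. = FALSE)
}
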