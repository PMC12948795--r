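test_that("one-way ANOVA matches the sums-of-squares oracle and handles identity", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- oneway_anova_posthoc(g)
  expect_equal(res$F, 0)
  expect_equal(res$partial_eta_sq, 0)
  # df formula on realistic unequal group sizes
  set.seed(2)
  sizes <- c(15, 15, 13, 16, 16)
  g5 <- lapply(sizes, function(n) rnorm(n))
  names(g5) <- paste0("g", 1:5)
  res5 <- oneway_anova_posthoc(g5)
  expect_equal(res5$df_between, 4)
  expect_equal(res5$df_within, 70)
  expect_equal(nrow(res5$pairwise), 10)
  expect_error(oneway_anova_posthoc(list(a = 1, b = c(1, 2))), "at least 2 values")
})

test_that("Bonferroni p-values are the raw pooled-t p-values times the family size", {
  set.seed(3)
  g <- lapply(1:5, function(i) rnorm(10, mean = i / 2))
  names(g) <- letters[1:5]
  res <- oneway_anova_posthoc(g)
  expect_equal(res$pairwise$bonferroni_p, pmin(1, res$pairwise$raw_p * 10))
  # oracle: stats::pairwise.t.test with bonferroni adjustment
  v <- unlist(g)
  grp <- factor(rep(names(g), each = 10))
  oracle <- stats::pairwise.t.test(v, grp, p.adjust.method = "bonferroni")$p.value
  for (r in seq_len(nrow(res$pairwise))) {
    i <- res$pairwise$group_i[r]
    j <- res$pairwise$group_j[r]
    expect_equal(res$pairwise$bonferroni_p[r], oracle[j, i], tolerance = 1e-12)
  }
})

test_that("analysis table assembly joins, drops and counts correctly", {
  cfg <- tiny_config(seed = 5L, nonwear_gap_probability = 0)
  study <- simulate_study(cfg)
  scores <- chronocog:::score_cmq_cohort(study$cohort)
  assignments <- assign_quintiles(scores)
  feats <- dplyr::bind_rows(lapply(study$series, function(s) {
    tibble::tibble(
      participant_id = attr(s, "participant_id"),
      included = TRUE
    )
  }))
  summaries <- suppressWarnings(summarize_sessions(study$trials)) |>
    exclude_low_engagement()
  tab <- suppressMessages(assemble_analysis_table(
    feats, assignments, summaries, study$cohort, study$series
  ))
  n_sessions_kept <- sum(!summaries$excluded & !is.na(summaries$mean_rt_ms))
  expect_equal(sum(tab$outcome_name == "rt"), n_sessions_kept)
  # no exclusions and full outcomes -> participants x sessions x tasks rows
  if (all(!summaries$excluded) && !anyNA(summaries$mean_rt_ms)) {
    expect_equal(sum(tab$outcome_name == "rt"), 8 * 6 * 2)
  }
  # wear-excluded participant disappears from every row
  feats2 <- feats
  feats2$included[feats2$participant_id == "P003"] <- FALSE
  tab2 <- suppressMessages(assemble_analysis_table(
    feats2, assignments, summaries, study$cohort, study$series
  ))
  expect_false("P003" %in% tab2$participant_id)
  expect_equal(
    sum(tab2$outcome_name == "errors"),
    sum(tab$outcome_name == "errors" & tab$participant_id != "P003")
  )
  # flagging k extra sessions drops exactly k rows per outcome
  summaries3 <- summaries
  idx <- which(!summaries3$excluded)[1:3]
  summaries3$excluded[idx] <- TRUE
  tab3 <- suppressMessages(assemble_analysis_table(
    feats, assignments, summaries3, study$cohort, study$series
  ))
  expect_equal(
    sum(tab3$outcome_name == "errors"),
    sum(tab$outcome_name == "errors") - 3
  )
  # corrupt join: summaries for an unknown participant
  bad <- summaries
  bad$participant_id[1] <- "P999"
  expect_error(
    assemble_analysis_table(feats, assignments, bad, study$cohort, study$series),
    "P999"
  )
})

test_that("the mixed model recovers a known signal and satisfies Wald consistency", {
  cfg <- simulation_config(n_participants = 40L, rng_seed = 11L)
  fit <- suppressWarnings(chronocog:::simulate_and_fit(cfg))
  expect_equal(fit$n_participants, 40)
  expect_false(anyNA(fit$terms$p))
  # Wald consistency: CI excludes 0 <=> p < 0.05
  excl <- fit$terms$ll > 0 | fit$terms$ul < 0
  expect_equal(excl, fit$terms$p < 0.05)
  expect_true(all(fit$terms$ll < fit$terms$estimate & fit$terms$estimate < fit$terms$ul))
  # the three headline terms carry the generative signs
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_lt(est[["time_of_day_h"]], 0)
  expect_lt(est[["chronotype_score"]], 0)
  expect_gt(est[["time_of_day_h:chronotype_score"]], 0)
  expect_gt(fit$var_intercept, 0)
})

test_that("with a single participant the model coincides with OLS", {
  # 12 sessions so one participant supports all eight fixed effects once the
  # person-constant covariates are replaced by varying ones
  cfg <- tiny_config(
    seed = 21L, n_days = 14L, session_days = 1:12,
    session_hours = rep(c(9, 21), 6)
  )
  study <- simulate_study(cfg)
  scores <- chronocog:::score_cmq_cohort(study$cohort)
  assignments <- assign_quintiles(scores)
  feats <- tibble::tibble(participant_id = "P001", included = TRUE)
  summaries <- suppressWarnings(
    summarize_sessions(study$trials[study$trials$participant_id == "P001", ])
  ) |> exclude_low_engagement()
  tab <- suppressMessages(assemble_analysis_table(
    feats, assignments, summaries, study$cohort, study$series["P001"]
  ))
  # person-constant covariates are unidentifiable with one participant, so
  # key artificial variation to the session
  sess <- as.integer(factor(tab$session_timestamp))
  tab$sex <- factor(c("female", "male")[sess %% 2 + 1],
    levels = c("female", "male")
  )
  tab$chronotype_score <- sess
  tab$caffeine_flag <- sess %% 3 != 0
  tab$age <- 18 + (sess * 7) %% 12
  expect_warning(fit <- fit_lmm(tab, outcome = "rt", task = "XNA1"), "OLS")
  ols <- lm(
    outcome_value ~ time_of_day_h * chronotype_score + age + sex +
      caffeine_flag + activity_prior_60min,
    data = tab[tab$outcome_name == "rt" & tab$task == "XNA1", ]
  )
  common <- intersect(fit$terms$term, names(coef(ols)))
  expect_equal(
    setNames(fit$terms$estimate, fit$terms$term)[common],
    coef(ols)[common]
  )
})

test_that("a collinear design fails naming the offending column", {
  cfg <- tiny_config(seed = 23L, nonwear_gap_probability = 0)
  # build a table and force collinearity: age identical to chronotype
  study <- simulate_study(cfg)
  scores <- chronocog:::score_cmq_cohort(study$cohort)
  assignments <- assign_quintiles(scores)
  feats <- tibble::tibble(
    participant_id = study$cohort$participant_id, included = TRUE
  )
  summaries <- suppressWarnings(summarize_sessions(study$trials)) |>
    exclude_low_engagement()
  tab <- suppressMessages(assemble_analysis_table(
    feats, assignments, summaries, study$cohort, study$series
  ))
  tab$age <- tab$chronotype_score
  expect_error(fit_lmm(tab, outcome = "rt", task = "XNA1"), "collinear")
})

test_that("error counts can be modelled as a Gaussian outcome", {
  cfg <- simulation_config(n_participants = 30L, rng_seed = 31L)
  study <- simulate_study(cfg)
  scores <- chronocog:::score_cmq_cohort(study$cohort)
  assignments <- assign_quintiles(scores)
  feats <- tibble::tibble(
    participant_id = study$cohort$participant_id, included = TRUE
  )
  summaries <- suppressWarnings(summarize_sessions(study$trials)) |>
    exclude_low_engagement()
  tab <- suppressMessages(assemble_analysis_table(
    feats, assignments, summaries, study$cohort, study$series
  ))
  fit <- suppressWarnings(fit_lmm(tab, outcome = "errors", task = "XNA2"))
  expect_equal(fit$terms$term[1], "(Intercept)")
  expect_true(all(is.finite(fit$terms$p)))
})

test_that("recovery experiments are deterministic and structurally sound", {
  cfg <- tiny_config(seed = 41L)
  rep1 <- recovery_experiment(cfg, n_replicates = 4, seed = 100)
  rep2 <- recovery_experiment(cfg, n_replicates = 4, seed = 100)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
  expect_equal(nrow(rep1), 8)
  expect_true(all(rep1$coverage >= 0 & rep1$coverage <= 1))
  expect_true(all(rep1$rejection_rate >= 0 & rep1$rejection_rate <= 1))
  expect_equal(attr(rep1, "n_replicates") + attr(rep1, "n_failed"), 4)
})

test_that("required sample size search matches a noncentral-F oracle", {
  n <- required_sample_anova_rm(
    effect_f = 0.2, n_groups = 5, n_measurements = 6,
    alpha = 0.05, power = 0.8, corr_rm = 0.5
  )
  power_at <- function(N) {
    lambda <- N * 6 * 0.2^2 / (1 + 5 * 0.5)
    1 - pf(qf(0.95, 4, N - 5), 4, N - 5, ncp = lambda)
  }
  # minimality: reaches the target at n, not at n - 1
  expect_gte(power_at(n), 0.8)
  expect_lt(power_at(n - 1), 0.8)
  # independent sweep oracle
  oracle <- 10
  while (power_at(oracle) < 0.8) oracle <- oracle + 1
  expect_equal(n, oracle)
  # monotone in effect size; degenerate floor as power -> 0
  expect_lt(
    required_sample_anova_rm(0.4, 5, 6, corr_rm = 0.5),
    n
  )
  expect_equal(required_sample_anova_rm(0.2, 5, 6, power = 1e-9), 10)
  expect_error(required_sample_anova_rm(1e-6, 5, 6, max_n = 500), "unreachable")
})

test_that("model-implied trajectories converge with the generative signs", {
  cfg <- simulation_config(n_participants = 40L, rng_seed = 51L)
  study <- simulate_study(cfg)
  scores <- chronocog:::score_cmq_cohort(study$cohort)
  assignments <- assign_quintiles(scores)
  feats <- tibble::tibble(
    participant_id = study$cohort$participant_id, included = TRUE
  )
  summaries <- suppressWarnings(summarize_sessions(study$trials)) |>
    exclude_low_engagement()
  tab <- suppressMessages(assemble_analysis_table(
    feats, assignments, summaries, study$cohort, study$series
  ))
  fit <- suppressWarnings(fit_lmm(tab, outcome = "rt", task = "XNA1"))
  traj <- predict_trajectories(fit, tab, hours = c(9, 21))
  spread <- tapply(traj$predicted, traj$time_of_day_h, function(v) diff(range(v)))
  expect_lt(spread[["21"]], spread[["9"]])
})
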