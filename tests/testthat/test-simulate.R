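test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_participants = 4), "n_participants")
  expect_error(simulation_config(epoch_seconds = 7), "epoch_seconds")
  expect_error(simulation_config(residual_rt_sd = -1), "residual_rt_sd")
  expect_error(simulation_config(nonwear_gap_probability = 2), "nonwear_gap_probability")
  expect_error(simulation_config(chronotype_range = c(10, 55)), "chronotype_range")
  expect_error(simulation_config(session_days = 1:8), "session_days")
})

test_that("cohort generation matches the target marginals and is deterministic", {
  cfg <- simulation_config(n_participants = 75L, rng_seed = 1L)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 75)
  expect_true(all(cohort$age >= 18 & cohort$age <= 30))
  expect_true(all(cohort$latent_chronotype >= 13 & cohort$latent_chronotype <= 55))
  expect_true(all(cohort$activity_acrophase >= 0 & cohort$activity_acrophase < 24))
  expect_identical(cohort, generate_cohort(cfg))
  # large-sample check of the truncated-normal age model (truncation to
  # [18, 30] pulls the mean slightly below 25)
  big <- generate_cohort(simulation_config(n_participants = 10000L, rng_seed = 2L))
  expect_gt(mean(big$age), 24)
  expect_lt(mean(big$age), 26)
  expect_gt(mean(big$sex == "female"), 0.53)
  expect_lt(mean(big$sex == "female"), 0.61)
})

test_that("degenerate cosinor settings produce the analytic series", {
  cfg <- simulation_config(
    activity_amplitude = 0, activity_amplitude_sd = 0, activity_noise_sd = 0,
    bout_rate_per_day = 0, nonwear_gap_probability = 0, activity_mesor = 321
  )
  p <- generate_cohort(cfg)[1, ]
  p$activity_amplitude <- 0
  s <- simulate_actigraphy(p, cfg)
  expect_equal(nrow(s), 7 * 1440)
  expect_true(all(s$vm == 321))
  # pure cosinor: argmax of the daily profile at the acrophase
  p2 <- p
  p2$activity_amplitude <- 800
  p2$activity_acrophase <- 14
  s2 <- simulate_actigraphy(p2, cfg)
  day1 <- s2$vm[1:1440]
  expect_equal(which.max(day1), 14 * 60 + 1)
})

test_that("acrophase shifts linearly with chronotype at the configured slope", {
  cfg <- simulation_config(acrophase_sd = 0, acrophase_slope = -0.1)
  p <- generate_cohort(cfg)[1:2, ]
  p$latent_chronotype <- c(30, 40)
  acro <- (cfg$acrophase_base + cfg$acrophase_slope * (p$latent_chronotype - 34)) %% 24
  expect_equal(acro[2] - acro[1], -1.0)
})

test_that("simulated CMQ sheets rescore to the rounded latent chronotype", {
  cfg <- tiny_config()
  # saturation at the scale ends
  for (latent in c(13, 55)) {
    sel <- simulate_cmq(list(latent_chronotype = latent), cfg)
    expect_equal(score_cmq(sel), latent)
  }
  sel_max <- simulate_cmq(list(latent_chronotype = 55), cfg)
  key <- cmq_default_key()
  expect_equal(unname(sel_max), as.integer(tapply(key$option, key$item, max)))
  expect_equal(unname(simulate_cmq(list(latent_chronotype = 13), cfg)), rep(1L, 13))
  # round trip across the whole scale, including fractional latents
  for (latent in seq(13, 55, by = 0.7)) {
    sel <- simulate_cmq(list(latent_chronotype = latent), cfg)
    expect_equal(score_cmq(sel), round(latent))
  }
})

test_that("sessions hold 17 XNA1 and 27 XNA2 trials at morning/evening targets", {
  cfg <- tiny_config()
  cohort <- generate_cohort(cfg)
  p <- cohort[1, ]
  s <- simulate_actigraphy(p, cfg)
  tr <- simulate_sessions(p, s, cfg)
  counts <- dplyr::count(tr, session_timestamp, task)
  expect_equal(nrow(counts), 12) # 6 sessions x 2 tasks
  expect_true(all(counts$n[counts$task == "XNA1"] == 17))
  expect_true(all(counts$n[counts$task == "XNA2"] == 27))
  expect_identical(tr, simulate_sessions(p, s, cfg))
  # later chronotypes test later: zero jitter isolates the lateness term
  cfg0 <- tiny_config(session_jitter_sd_min = 0)
  early <- p
  early$latent_chronotype <- 55
  late <- p
  late$latent_chronotype <- 15
  t_e <- unique(simulate_sessions(early, s, cfg0)$session_timestamp)
  t_l <- unique(simulate_sessions(late, s, cfg0)$session_timestamp)
  expect_true(all(t_l > t_e))
  expect_equal(
    as.numeric(t_l[1] - t_e[1], units = "mins"),
    cfg0$lateness_slope_min_per_point * 40
  )
})

test_that("a degenerate generative model returns the intercept exactly", {
  cfg <- tiny_config(
    beta_time = 0, beta_chronotype = 0, beta_interaction = 0, beta_age = 0,
    beta_sex = 0, beta_caffeine = 0, beta_activity = 0, beta_task_xna2 = 0,
    random_intercept_sd = 0, session_noise_sd = 0, residual_rt_sd = 0
  )
  p <- generate_cohort(cfg)[1, ]
  p$random_intercept <- 0
  s <- simulate_actigraphy(p, cfg)
  tr <- simulate_sessions(p, s, cfg)
  expect_true(all(abs(tr$rt_ms - cfg$beta_intercept) < 1e-9))
})

test_that("session times outside the actigraphy span raise a generation error", {
  cfg <- tiny_config()
  p <- generate_cohort(cfg)[1, ]
  short <- simulate_actigraphy(p, simulation_config(
    n_days = 2L, session_days = 1:2, session_hours = c(9, 21),
    n_participants = 8L
  ))
  expect_error(simulate_sessions(p, short, cfg), "outside")
})

test_that("the morning RT gap between late and early chronotypes closes by evening", {
  # with beta_chronotype < 0 and beta_interaction > 0, low scorers (late
  # chronotypes) are slower in the morning and converge towards the evening
  cfg <- tiny_config(
    session_jitter_sd_min = 0, lateness_slope_min_per_point = 0,
    random_intercept_sd = 0, session_noise_sd = 0, residual_rt_sd = 0,
    beta_caffeine = 0, beta_activity = 0
  )
  p <- generate_cohort(cfg)[1, ]
  p$random_intercept <- 0
  s <- simulate_actigraphy(p, cfg)
  rt_for <- function(latent) {
    q <- p
    q$latent_chronotype <- latent
    tr <- simulate_sessions(q, s, cfg)
    tr <- tr[tr$task == "XNA1", ]
    tapply(tr$rt_ms, hours_since_midnight(tr$session_timestamp), mean)
  }
  lo <- rt_for(15) # late chronotype
  hi <- rt_for(53) # early chronotype
  gap <- lo - hi
  expect_true(all(gap[names(gap) == "9"] > gap[names(gap) == "21"]))
  expect_true(all(gap > 0)) # late chronotypes slower throughout under these betas
})

test_that("a whole simulated study is reproducible byte for byte", {
  cfg <- tiny_config(seed = 33L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$series[[3]]$vm, s2$series[[3]]$vm)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study_csv(s1, d1)
  write_study_csv(s2, d2)
  for (f in c("cohort.csv", "trials.csv", file.path("epochs", "P001.csv"))) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f))
    )
  }
})

test_that("the marginal time-of-day slope matches its analytic expectation", {
  # with interaction bct, the expected slope of session-mean RT on time of
  # day is bt + bct * E[C]; check by OLS on a large simulated cohort
  cfg <- simulation_config(
    n_participants = 400L, rng_seed = 8L,
    nonwear_gap_probability = 0
  )
  study <- simulate_study(cfg)
  smry <- suppressWarnings(summarize_sessions(study$trials))
  smry <- smry[smry$task == "XNA1", ]
  slope <- coef(lm(mean_rt_ms ~ time_of_day_h, data = smry))[2]
  expected <- cfg$beta_time + cfg$beta_interaction * 34
  expect_lt(abs(slope - expected), 1.5)
})
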