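# Synthetic free-living cohort generator. Emulates the structure the analysis
# assumes: ~75 young adults wearing a wrist accelerometer for 7 days, a 13-item
# morningness questionnaire, and 6 mobile cognitive sessions (3 near 09:00, 3
# near 21:00 on alternating days) whose reaction-time and error outcomes follow
# a linear predictor with a chronotype-by-time-of-day interaction.

#' Simulation configuration
#'
#' Holds every generative parameter. The defaults describe the study
#' conditions the package targets: 75 participants aged 18-30 (mean 25, SD 7,
#' 57% female), 7 days of 60-s epochs, six sessions near 09:00/21:00, and
#' reaction-time coefficients matching the reported XNA1 fixed effects
#' (intercept 1195.21 ms, time of day -15.65 ms/h, chronotype -13.39 ms/point,
#' interaction +0.54 ms/(point*h), age 7.39, sex(male) 12.15, caffeine 29.68,
#' prior-hour activity -3e-5).
#'
#' @param n_participants cohort size (>= 5 so quintiles are possible).
#' @param n_days days of actigraphy per participant.
#' @param epoch_seconds epoch width; must divide 3600.
#' @param session_days,session_hours per-session target day (1-based) and
#'   local clock hour; defaults: days 1-6 alternating 09:00 / 21:00.
#' @param rng_seed integer seed; identical config + seed gives identical data.
#' @param start_date first monitoring day (local, timezone-naive).
#' @param beta_intercept,beta_time,beta_chronotype,beta_interaction,beta_age,beta_sex,beta_caffeine,beta_activity
#'   fixed effects of the reaction-time linear predictor (ms units; time in
#'   hours since midnight, chronotype in CMQ points).
#' @param beta_task_xna2 additive XNA2 intercept offset (ms).
#' @param random_intercept_sd SD of the per-participant random intercept (ms).
#' @param session_noise_sd SD of a session-level mean-zero state term (ms)
#'   capturing day-to-day arousal/environment variability of home testing.
#' @param residual_rt_sd trial-level reaction-time SD (ms); trials follow a
#'   shifted lognormal (shift `rt_shift`) whose median equals the linear
#'   predictor.
#' @param rt_shift lognormal shift (ms, default 125).
#' @param gamma_intercept,gamma_time,gamma_chronotype,gamma_interaction,gamma_age,gamma_sex,gamma_caffeine,gamma_activity
#'   logit-scale coefficients of the per-trial error model.
#' @param activity_mesor,activity_amplitude,activity_amplitude_sd cosinor
#'   mesor and amplitude (vector-magnitude units) of the diurnal activity
#'   rhythm; amplitudes vary across participants.
#' @param acrophase_base mean clock hour of peak activity at the chronotype
#'   midpoint (34 points).
#' @param acrophase_slope hours of acrophase shift per CMQ point (negative:
#'   earlier chronotypes peak earlier).
#' @param acrophase_sd between-participant acrophase SD (h).
#' @param bout_rate_per_day,bout_duration_min,bout_magnitude Poisson-timed
#'   activity bouts superimposed on the cosinor.
#' @param activity_noise_sd half-normal epoch noise SD.
#' @param nonwear_gap_probability per-day probability of inserting a zero-run
#'   non-wear gap.
#' @param nonwear_gap_minutes range (min, max) of gap lengths in minutes.
#' @param session_jitter_sd_min Gaussian session-timing jitter SD (minutes).
#' @param lateness_slope_min_per_point minutes of extra delay per CMQ point
#'   below 55 (later chronotypes test later).
#' @param caffeine_propensity_range per-participant caffeine propensity drawn
#'   uniformly from this range.
#' @param caffeine_threshold_mg dose counted as a "yes" (one espresso, 200 mg).
#' @param chronotype_range latent chronotype drawn uniformly over this range
#'   (default the full 13-55 scale, so all five quintiles are populated).
#' @return object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_participants = 75L, n_days = 7L,
                              epoch_seconds = 60L,
                              session_days = 1:6,
                              session_hours = c(9, 21, 9, 21, 9, 21),
                              rng_seed = 1L,
                              start_date = "2024-01-01",
                              beta_intercept = 1195.21, beta_time = -15.65,
                              beta_chronotype = -13.39, beta_interaction = 0.54,
                              beta_age = 7.39, beta_sex = 12.15,
                              beta_caffeine = 29.68, beta_activity = -3e-5,
                              beta_task_xna2 = 16.5,
                              random_intercept_sd = 150, session_noise_sd = 100,
                              residual_rt_sd = 250, rt_shift = 125,
                              gamma_intercept = -2.2, gamma_time = -0.02,
                              gamma_chronotype = -0.012,
                              gamma_interaction = 6e-4,
                              gamma_age = 0, gamma_sex = 0, gamma_caffeine = 0,
                              gamma_activity = 0,
                              activity_mesor = 1500, activity_amplitude = 1200,
                              activity_amplitude_sd = 300,
                              acrophase_base = 14, acrophase_slope = -0.1,
                              acrophase_sd = 0.5,
                              bout_rate_per_day = 1, bout_duration_min = 30,
                              bout_magnitude = 2000, activity_noise_sd = 500,
                              nonwear_gap_probability = 0.05,
                              nonwear_gap_minutes = c(60, 180),
                              session_jitter_sd_min = 20,
                              lateness_slope_min_per_point = 0.5,
                              caffeine_propensity_range = c(0.1, 0.5),
                              caffeine_threshold_mg = 200,
                              chronotype_range = c(13, 55)) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid configuration: `%s` %s", field, why), call. = FALSE)
  }
  if (cfg$n_participants < 5) fail("n_participants", "must be >= 5")
  if (cfg$n_days < 1) fail("n_days", "must be >= 1")
  if (3600 %% cfg$epoch_seconds != 0) fail("epoch_seconds", "must divide 3600")
  if (length(cfg$session_days) != length(cfg$session_hours)) {
    fail("session_hours", "must match session_days in length")
  }
  if (any(cfg$session_days > cfg$n_days)) {
    fail("session_days", "must lie within the monitoring period")
  }
  for (f in c(
    "random_intercept_sd", "session_noise_sd", "residual_rt_sd",
    "activity_amplitude_sd", "acrophase_sd", "bout_rate_per_day",
    "activity_noise_sd", "session_jitter_sd_min"
  )) {
    if (cfg[[f]] < 0) fail(f, "must be nonnegative")
  }
  if (cfg$nonwear_gap_probability < 0 || cfg$nonwear_gap_probability > 1) {
    fail("nonwear_gap_probability", "must be in [0, 1]")
  }
  if (cfg$chronotype_range[1] < 13 || cfg$chronotype_range[2] > 55 ||
    diff(cfg$chronotype_range) < 0) {
    fail("chronotype_range", "must be within [13, 55]")
  }
  invisible(cfg)
}

#' Generate participant profiles for a synthetic cohort
#'
#' Ages are drawn from a normal with mean 25 and SD 7 truncated to
#' `[18, 30]`; sex is female with probability 0.57; latent chronotype is
#' uniform over `chronotype_range`. Each profile also carries its individual
#' random intercept, activity amplitude and acrophase (acrophase decreasing in
#' chronotype at `acrophase_slope` h/point), caffeine propensity, body
#' measures, and a derived per-participant RNG seed so that downstream
#' simulation is reproducible participant-by-participant.
#'
#' @param config a [simulation_config()].
#' @return tibble of participant profiles.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$rng_seed)
  generate_cohort_impl(config)
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  age <- stats::rnorm(n, 25, 7)
  while (any(bad <- age < 18 | age > 30)) {
    age[bad] <- stats::rnorm(sum(bad), 25, 7)
  }
  sex <- ifelse(stats::runif(n) < 0.57, "female", "male")
  chron <- stats::runif(n, cfg$chronotype_range[1], cfg$chronotype_range[2])
  u <- stats::rnorm(n, 0, cfg$random_intercept_sd)
  amp <- pmax(0, stats::rnorm(n, cfg$activity_amplitude, cfg$activity_amplitude_sd))
  acro <- (cfg$acrophase_base +
    cfg$acrophase_slope * (chron - 34) +
    stats::rnorm(n, 0, cfg$acrophase_sd)) %% 24
  caf <- stats::runif(
    n, cfg$caffeine_propensity_range[1], cfg$caffeine_propensity_range[2]
  )
  height_m <- stats::rnorm(n, 1.70, 0.09)
  bmi <- stats::rnorm(n, 22.9, 2.8)
  wthr <- stats::rnorm(n, 0.47, 0.05)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = age,
    sex = sex,
    latent_chronotype = chron,
    random_intercept = u,
    activity_amplitude = amp,
    activity_acrophase = acro,
    caffeine_propensity = caf,
    height_m = height_m,
    mass_kg = bmi * height_m^2,
    waist_cm = wthr * height_m * 100,
    seed = vapply(seq_len(n), function(i) participant_seed(cfg$rng_seed, i),
      integer(1)
    )
  )
}

#' Simulate a 7-day epoch actigraphy series for one participant
#'
#' The diurnal profile is a cosinor, `mesor + A*cos(2*pi*(t - acrophase)/24)`,
#' clipped at zero, plus Poisson-timed activity bouts and half-normal epoch
#' noise. Optional non-wear gaps (contiguous zero runs) are inserted per day
#' with probability `nonwear_gap_probability` to exercise the wear-time
#' filter. Deterministic given the profile's seed.
#'
#' @param profile one row of [generate_cohort()] output.
#' @param config a [simulation_config()].
#' @return an [epoch_series()].
#' @export
simulate_actigraphy <- function(profile, config) {
  validate_config(config)
  set.seed(profile$seed + 1L)
  simulate_actigraphy_impl(profile, config)
}

simulate_actigraphy_impl <- function(profile, cfg) {
  eps <- cfg$epoch_seconds
  per_day <- 86400 / eps
  n <- cfg$n_days * per_day
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  tod <- ((seq_len(n) - 1) * eps / 3600) %% 24
  vm <- pmax(0, cfg$activity_mesor + profile$activity_amplitude *
    cos(2 * pi * (tod - profile$activity_acrophase) / 24))
  if (cfg$bout_rate_per_day > 0) {
    nb <- stats::rpois(1, cfg$bout_rate_per_day * cfg$n_days)
    if (nb > 0) {
      dur <- max(1L, round(cfg$bout_duration_min * 60 / eps))
      starts <- sample.int(n, nb, replace = TRUE)
      for (s in starts) {
        idx <- s:min(n, s + dur - 1L)
        vm[idx] <- vm[idx] + cfg$bout_magnitude
      }
    }
  }
  if (cfg$activity_noise_sd > 0) {
    vm <- vm + abs(stats::rnorm(n, 0, cfg$activity_noise_sd))
  }
  if (cfg$nonwear_gap_probability > 0) {
    for (d in seq_len(cfg$n_days)) {
      if (stats::runif(1) < cfg$nonwear_gap_probability) {
        len_min <- stats::runif(
          1, cfg$nonwear_gap_minutes[1], cfg$nonwear_gap_minutes[2]
        )
        len <- max(1L, round(len_min * 60 / eps))
        start <- (d - 1L) * per_day +
          sample.int(max(1L, per_day - len), 1L)
        vm[start:min(n, start + len - 1L)] <- 0
      }
    }
  }
  new_epoch_series(t0 + (seq_len(n) - 1) * eps, vm,
    participant_id = profile$participant_id, epoch_seconds = eps
  )
}

#' Simulate a CMQ response sheet matching a latent chronotype
#'
#' Builds a 13-item response whose total score under [score_cmq()] equals the
#' profile's latent chronotype rounded to the nearest achievable total:
#' starting from all-minimum selections, points are allocated greedily across
#' items up to each item's maximum. The round trip
#' `score_cmq(simulate_cmq(p))` therefore equals `round(latent)` exactly.
#'
#' @param profile one row of [generate_cohort()] output (or any list with a
#'   `latent_chronotype` field).
#' @param config a [simulation_config()] (unused beyond validation; the
#'   allocation is deterministic).
#' @param key scoring key, see [cmq_default_key()].
#' @return named integer vector `cmq_01`..`cmq_13` of selected option indices.
#' @export
simulate_cmq <- function(profile, config = simulation_config(), key = cmq_default_key()) {
  validate_cmq_key(key)
  target <- max(13L, min(55L, as.integer(round(profile$latent_chronotype))))
  maxima <- tapply(key$points, key$item, max)
  extra <- target - 13L
  sel <- rep(1L, 13L)
  for (i in seq_len(13L)) {
    add <- min(extra, maxima[[i]] - 1L)
    sel[i] <- sel[i] + add
    extra <- extra - add
  }
  stats::setNames(sel, sprintf("cmq_%02d", 1:13))
}

#' Simulate the six cognitive sessions for one participant
#'
#' Sessions are placed at the configured target times plus Gaussian jitter
#' plus a chronotype-dependent lateness term (later chronotypes test later).
#' Each session holds one XNA1 block of 17 trials and one XNA2 block of 27
#' trials. Trial reaction times follow a shifted lognormal whose median equals
#' the linear predictor
#' `b0 + bt*t + bc*C + bct*C*t + b_age*age + b_sex*male + b_caf*caffeine +
#' b_act*AUC60(t) + u_i + e_s`, with `t` the realised time of day in hours,
#' `C` the (rounded) chronotype score, `AUC60` the prior-hour activity
#' computed from the supplied epoch series, `u_i` the participant random
#' intercept and `e_s` a session-level state term. Correctness is Bernoulli
#' with a logit-linear analogue; the caffeine dose is drawn from the
#' participant's propensity. Deterministic given the profile's seed.
#'
#' @param profile one row of [generate_cohort()] output.
#' @param series the participant's [epoch_series()] (must span the sessions).
#' @param config a [simulation_config()].
#' @return tibble of trial records: `participant_id`, `task`,
#'   `session_timestamp`, `trial_index`, `rt_ms`, `correct`, `caffeine_mg`.
#' @export
simulate_sessions <- function(profile, series, config) {
  validate_config(config)
  set.seed(profile$seed + 3L)
  simulate_sessions_impl(profile, series, config)
}

simulate_sessions_impl <- function(profile, series, cfg) {
  n_s <- length(cfg$session_days)
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  targets <- t0 + (cfg$session_days - 1) * 86400 + cfg$session_hours * 3600
  jitter_s <- stats::rnorm(n_s, 0, cfg$session_jitter_sd_min) * 60
  late_s <- cfg$lateness_slope_min_per_point *
    (55 - profile$latent_chronotype) * 60
  ts <- targets + jitter_s + late_s
  span_end <- series$timestamp[nrow(series)] + es_epoch_seconds(series)
  if (any(ts < series$timestamp[1] | ts > span_end)) {
    stop("session time falls outside the actigraphy span", call. = FALSE)
  }
  auc60 <- vapply(
    seq_len(n_s),
    function(s) activity_prior_window(series, ts[s]), numeric(1)
  )
  auc60[is.na(auc60)] <- 0
  consumed <- stats::runif(n_s) < profile$caffeine_propensity
  caffeine_mg <- ifelse(consumed, round(stats::runif(n_s, 80, 350)), 0)
  caffeine_yes <- caffeine_mg >= cfg$caffeine_threshold_mg
  t_h <- hours_since_midnight(ts)
  C <- round(profile$latent_chronotype)
  male <- as.numeric(profile$sex == "male")
  e_s <- stats::rnorm(n_s, 0, cfg$session_noise_sd)
  n_trials <- c(XNA1 = 17L, XNA2 = 27L)
  # one block row per session x task, then expanded to trial level
  blk_s <- rep(seq_len(n_s), each = 2L)
  blk_task <- rep(c("XNA1", "XNA2"), times = n_s)
  blk_nt <- n_trials[blk_task]
  lp <- cfg$beta_intercept +
    (blk_task == "XNA2") * cfg$beta_task_xna2 +
    cfg$beta_time * t_h[blk_s] +
    cfg$beta_chronotype * C +
    cfg$beta_interaction * C * t_h[blk_s] +
    cfg$beta_age * profile$age +
    cfg$beta_sex * male +
    cfg$beta_caffeine * caffeine_yes[blk_s] +
    cfg$beta_activity * auc60[blk_s] +
    profile$random_intercept + e_s[blk_s]
  med <- lp - cfg$rt_shift
  if (any(med <= 0)) {
    stop("linear predictor fell at or below the lognormal shift; ",
      "check the effect coefficients",
      call. = FALSE
    )
  }
  sigma <- if (cfg$residual_rt_sd > 0) cfg$residual_rt_sd / med else rep(0, length(med))
  p_err <- stats::plogis(
    cfg$gamma_intercept +
      cfg$gamma_time * t_h[blk_s] +
      cfg$gamma_chronotype * C +
      cfg$gamma_interaction * C * t_h[blk_s] +
      cfg$gamma_age * profile$age +
      cfg$gamma_sex * male +
      cfg$gamma_caffeine * caffeine_yes[blk_s] +
      cfg$gamma_activity * auc60[blk_s]
  )
  i <- rep(seq_along(blk_s), times = blk_nt) # trial -> block index
  n_tr <- length(i)
  rt <- cfg$rt_shift + med[i] * exp(stats::rnorm(n_tr, 0, sigma[i]))
  correct <- stats::runif(n_tr) >= p_err[i]
  tibble::new_tibble(list(
    participant_id = rep(profile$participant_id, n_tr),
    task = blk_task[i],
    session_timestamp = ts[blk_s[i]],
    trial_index = unlist(lapply(blk_nt, seq_len), use.names = FALSE),
    rt_ms = rt,
    correct = correct,
    caffeine_mg = caffeine_mg[blk_s[i]]
  ), nrow = n_tr)
}

#' Simulate a complete synthetic study
#'
#' Runs [generate_cohort()], then per participant [simulate_actigraphy()],
#' [simulate_cmq()] and [simulate_sessions()]. Fully deterministic under
#' `config$rng_seed`.
#'
#' @param config a [simulation_config()].
#' @param key CMQ scoring key.
#' @return list with `config`, `cohort` (profiles + demographics + CMQ item
#'   columns), `series` (named list of [epoch_series()]), `trials` (trial
#'   table across all participants).
#' @export
simulate_study <- function(config = simulation_config(), key = cmq_default_key()) {
  cohort <- generate_cohort(config)
  n <- nrow(cohort)
  series <- vector("list", n)
  trials <- vector("list", n)
  cmq <- matrix(NA_integer_, n, 13L)
  for (i in seq_len(n)) {
    p <- cohort[i, ]
    set.seed(p$seed + 1L)
    series[[i]] <- simulate_actigraphy_impl(p, config)
    cmq[i, ] <- simulate_cmq(p, config, key)
    set.seed(p$seed + 3L)
    trials[[i]] <- simulate_sessions_impl(p, series[[i]], config)
  }
  names(series) <- cohort$participant_id
  colnames(cmq) <- sprintf("cmq_%02d", 1:13)
  list(
    config = config,
    cohort = dplyr::bind_cols(cohort, tibble::as_tibble(cmq)),
    series = series,
    trials = dplyr::bind_rows(trials)
  )
}

#' Write a simulated study to CSV files
#'
#' Emits `cohort.csv` (demographics + CMQ item responses), `trials.csv`
#' (trial-level cognitive log) and one `epochs/<participant>.csv` per
#' participant (`timestamp`, `vector_magnitude`). Timestamps are ISO-8601;
#' identical config + seed yields byte-identical files.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  cohort <- study$cohort[, c(
    "participant_id", "age", "sex", "height_m", "mass_kg", "waist_cm",
    sprintf("cmq_%02d", 1:13)
  )]
  readr::write_csv(cohort, file.path(dir, "cohort.csv"))
  trials <- study$trials
  trials$session_timestamp <- format(trials$session_timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(trials, file.path(dir, "trials.csv"))
  for (id in names(study$series)) {
    write_epoch_csv(study$series[[id]], file.path(dir, "epochs", paste0(id, ".csv")))
  }
  invisible(dir)
}
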