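# fixture builders and independent brute-force oracles used across tests

T0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

make_series <- function(vm, start = T0, eps = 60, id = "T01") {
  epoch_series(start + (seq_along(vm) - 1) * eps, vm,
    participant_id = id, epoch_seconds = eps
  )
}

# constant-signal 7-day series
flat_week <- function(value = 100) make_series(rep(value, 7 * 1440))

# cosinor series (no noise) over n_days
cosinor_series <- function(mesor, amplitude, acrophase, n_days = 7, eps = 60) {
  n <- n_days * 86400 / eps
  tod <- ((seq_len(n) - 1) * eps / 3600) %% 24
  make_series(pmax(0, mesor + amplitude * cos(2 * pi * (tod - acrophase) / 24)),
    eps = eps
  )
}

# --- independent oracles (naive loops, no shared code with the package) ---

oracle_rollsum <- function(vm, k) {
  n <- length(vm)
  out <- rep(NA_real_, n - k + 1)
  for (i in k:n) out[i - k + 1] <- sum(vm[(i - k + 1):i])
  out
}

oracle_circmean <- function(hours) {
  a <- hours / 24 * 2 * pi
  m <- atan2(sum(sin(a)) / length(a), sum(cos(a)) / length(a))
  h <- (m / (2 * pi) * 24) %% 24
  if (24 - h < 1e-9) h <- 0
  h
}

oracle_daily_peaks <- function(window_end, auc, eps = 60, min_cov = 0.5) {
  day <- as.Date(window_end, tz = "UTC")
  out <- numeric(0)
  for (d in sort(unique(day))) {
    v <- auc[day == d]
    we <- window_end[day == d]
    if (sum(!is.na(v)) < min_cov * 86400 / eps) next
    best <- which(!is.na(v) & v == max(v, na.rm = TRUE))[1]
    lt <- as.POSIXlt(we[best], tz = "UTC")
    out <- c(out, lt$hour + lt$min / 60 + lt$sec / 3600)
  }
  out
}

oracle_anova <- function(groups) {
  # direct sums-of-squares computation
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups)
  n <- length(all_v)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(
    F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
    eta = ssb / (ssb + ssw), df1 = k - 1, df2 = n - k
  )
}

# minimal trial table for cognition tests
make_trials <- function(rt, correct = rep(TRUE, length(rt)),
                        task = "XNA1", caffeine_mg = 0,
                        ts = T0 + 9 * 3600, id = "T01") {
  tibble::tibble(
    participant_id = id, task = task, session_timestamp = ts,
    trial_index = seq_along(rt), rt_ms = rt, correct = correct,
    caffeine_mg = caffeine_mg
  )
}

# small, fast simulation config for structural tests
tiny_config <- function(seed = 1L, ...) {
  simulation_config(n_participants = 8L, rng_seed = seed, ...)
}
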