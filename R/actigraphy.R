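# Activity feature extraction from 60-s epoch vector-magnitude series.
#
# Conventions shared by every operation here:
#  * windows are trailing and half-open, (t - window, t], indexed by their end
#    time, so the rolling AUC and the "previous 60 min" covariate agree;
#  * AUC is the discrete sum of epoch values over the window (left Riemann sum
#    at epoch resolution) -- units are arbitrary activity units;
#  * non-wear = missing epochs plus any maximal run of >= `nonwear_zero_run_min`
#    consecutive zero epochs (a simple, documented, replaceable heuristic).

#' Fraction of the monitoring period the device was worn
#'
#' Non-wear is defined as missing epochs plus any maximal run of at least
#' `nonwear_zero_run_min` consecutive all-zero epochs. Participants with a
#' wear fraction strictly below 0.9 are conventionally excluded.
#'
#' @param series an [epoch_series()].
#' @param nonwear_zero_run_min minimum all-zero run length (minutes) counted
#'   as non-wear.
#' @return proportion in `[0, 1]`.
#' @export
compute_wear_fraction <- function(series, nonwear_zero_run_min = 60) {
  if (nrow(series) == 0L) stop("empty epoch series", call. = FALSE)
  eps <- es_epoch_seconds(series)
  run_len <- nonwear_zero_run_min * 60 / eps
  vm <- series$vm
  nonwear <- is.na(vm)
  is_zero <- !is.na(vm) & vm == 0
  r <- rle(is_zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  long_zero <- which(r$values & r$lengths >= run_len)
  for (j in long_zero) nonwear[starts[j]:ends[j]] <- TRUE
  1 - sum(nonwear) / length(vm)
}

#' Trailing rolling-window AUC of an epoch series
#'
#' For every epoch-boundary time `t` with a complete trailing window
#' `(t - window, t]`, the AUC is the sum of the epoch values in the window.
#' Windows containing any missing epoch are emitted as `NA`; times whose
#' window would extend before the series start are not emitted at all.
#'
#' @param series an [epoch_series()].
#' @param window_minutes window width in minutes; must be a multiple of the
#'   epoch length (default 60).
#' @return tibble of class `rolling_auc_series` with columns `window_end`
#'   (`POSIXct`, the end of the last epoch in the window) and `auc`.
#' @export
rolling_auc <- function(series, window_minutes = 60) {
  eps <- es_epoch_seconds(series)
  if ((window_minutes * 60) %% eps != 0) {
    stop("window must be a multiple of the epoch length", call. = FALSE)
  }
  k <- as.integer(window_minutes * 60 / eps)
  if (nrow(series) < k) stop("series shorter than one window", call. = FALSE)
  auc <- zoo::rollsum(series$vm, k = k, align = "right", fill = NA)
  idx <- k:nrow(series)
  out <- tibble::tibble(
    window_end = series$timestamp[idx] + eps,
    auc = auc[idx]
  )
  structure(out,
    class = c("rolling_auc_series", class(out)),
    participant_id = es_participant(series),
    epoch_seconds = eps,
    window_minutes = window_minutes
  )
}

#' Time of day of peak rolling AUC, one per calendar day
#'
#' Days run local midnight to midnight; a window belongs to the day containing
#' its end time. Each day's peak is the window-end time of day with maximal
#' AUC, ties broken by the earliest occurrence. Days where fewer than
#' `min_coverage` of the nominal number of windows are observed are skipped.
#'
#' @param auc a `rolling_auc_series` from [rolling_auc()].
#' @param min_coverage minimum fraction of a day's windows that must be
#'   non-missing (default 0.5).
#' @return numeric vector of clock hours in `[0, 24)`, one per qualifying day,
#'   named by date.
#' @export
daily_peak_times <- function(auc, min_coverage = 0.5) {
  if (nrow(auc) == 0L) stop("empty rolling AUC series", call. = FALSE)
  eps <- attr(auc, "epoch_seconds") %||% 60
  nominal <- 86400 / eps
  day <- as.Date(auc$window_end, tz = "UTC")
  tod <- hours_since_midnight(auc$window_end)
  peaks <- c()
  for (d in sort(unique(day))) {
    sel <- day == d
    v <- auc$auc[sel]
    if (sum(!is.na(v)) < min_coverage * nominal) next
    i <- which(v == max(v, na.rm = TRUE))[1] # earliest tie wins
    p <- tod[sel][i]
    names(p) <- format(as.Date(d, origin = "1970-01-01"))
    peaks <- c(peaks, p)
  }
  if (length(peaks) == 0L) stop("no day with sufficient window coverage", call. = FALSE)
  peaks
}

#' Average clock times across days
#'
#' Clock times live on a circle, so averaging maps each hour `h` to the angle
#' `2*pi*h/24`, averages the unit vectors and maps back; a 23:00/01:00 pair
#' correctly averages to midnight where the arithmetic mean would say noon.
#' The arithmetic mean is available for sensitivity analysis.
#'
#' @param peaks clock hours in `[0, 24)`.
#' @param method `"circular"` (default) or `"arithmetic"`.
#' @return mean clock hour in `[0, 24)`.
#' @export
mean_peak_time <- function(peaks, method = c("circular", "arithmetic")) {
  method <- match.arg(method)
  if (length(peaks) == 0L) stop("no peak times supplied", call. = FALSE)
  if (method == "arithmetic") return(mean(peaks))
  circular_mean_hours(peaks)
}

#' Total activity over the monitoring period
#'
#' Plain sum of all observed epoch vector magnitudes -- an arbitrary measure
#' of overall activity. Refuses participants failing the wear-time screen
#' unless `check_wear = FALSE`.
#'
#' @param series an [epoch_series()].
#' @param check_wear verify the 90% wear rule before summing.
#' @param wear_threshold exclusion threshold (strict `<`, default 0.9).
#' @param nonwear_zero_run_min passed to [compute_wear_fraction()].
#' @return total activity (arbitrary units).
#' @export
total_auc <- function(series, check_wear = TRUE, wear_threshold = 0.9,
                      nonwear_zero_run_min = 60) {
  if (check_wear) {
    wf <- compute_wear_fraction(series, nonwear_zero_run_min)
    if (wf < wear_threshold) {
      stop(sprintf(
        "participant %s excluded: wear fraction %.3f < %.2f",
        es_participant(series), wf, wear_threshold
      ), call. = FALSE)
    }
  }
  sum(series$vm, na.rm = TRUE)
}

#' Activity in the window preceding a timestamp
#'
#' Sums epoch values over the trailing window `(at - window, at]` after
#' truncating `at` down to the nearest epoch boundary, matching the rolling
#' AUC convention exactly. Returns `NA` when the window is incomplete or
#' contains missing epochs.
#'
#' @param series an [epoch_series()].
#' @param at `POSIXct` timestamp within the series span.
#' @param window_minutes trailing window width (default 60).
#' @return activity units, or `NA` if the window is not fully observed.
#' @export
activity_prior_window <- function(series, at, window_minutes = 60) {
  eps <- es_epoch_seconds(series)
  k <- window_minutes * 60 / eps
  if (k %% 1 != 0) stop("window must be a multiple of the epoch length", call. = FALSE)
  t0 <- series$timestamp[1]
  span_end <- series$timestamp[nrow(series)] + eps
  if (at < t0 || at > span_end) {
    stop("timestamp outside the actigraphy span", call. = FALSE)
  }
  i_end <- floor(as.numeric(difftime(at, t0, units = "secs")) / eps)
  i_start <- i_end - k + 1
  if (i_start < 1 || i_end < 1) return(NA_real_)
  vals <- series$vm[i_start:i_end]
  if (anyNA(vals)) return(NA_real_)
  sum(vals)
}

#' Per-participant activity feature summary
#'
#' Combines the wear-time screen, 7-day total AUC, and the circular mean of
#' daily peak-activity times into one row per participant. Total AUC and peak
#' times are reported as `NA` for excluded participants.
#'
#' @param series an [epoch_series()].
#' @param window_minutes rolling window (default 60).
#' @param nonwear_zero_run_min non-wear run rule (default 60).
#' @param wear_threshold exclusion threshold (default 0.9, strict `<`).
#' @param peak_method passed to [mean_peak_time()].
#' @return one-row tibble: `participant_id`, `wear_fraction`, `included`,
#'   `total_auc_7day`, `mean_peak_time_h`, `daily_peaks` (semicolon list).
#' @export
activity_summary <- function(series, window_minutes = 60,
                             nonwear_zero_run_min = 60, wear_threshold = 0.9,
                             peak_method = "circular") {
  wf <- compute_wear_fraction(series, nonwear_zero_run_min)
  included <- wf >= wear_threshold
  tot <- NA_real_
  mpt <- NA_real_
  peaks_str <- NA_character_
  if (included) {
    tot <- total_auc(series, check_wear = FALSE)
    peaks <- daily_peak_times(rolling_auc(series, window_minutes))
    mpt <- mean_peak_time(peaks, method = peak_method)
    peaks_str <- paste(sprintf("%.4f", unname(peaks)), collapse = ";")
  }
  tibble::tibble(
    participant_id = es_participant(series),
    wear_fraction = wf,
    included = included,
    total_auc_7day = tot,
    mean_peak_time_h = mpt,
    daily_peaks = peaks_str
  )
}
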