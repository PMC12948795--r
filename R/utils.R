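# internal helpers shared across modules

#' Fractional hours since local midnight
#'
#' @param ts a `POSIXct` vector.
#' @return numeric hours in `[0, 24)`.
#' @export
hours_since_midnight <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# circular mean of clock hours; errors when the resultant vector vanishes
circular_mean_hours <- function(hours, period = 24, tol = 1e-9) {
  ang <- hours * 2 * pi / period
  x <- mean(cos(ang))
  y <- mean(sin(ang))
  if (sqrt(x^2 + y^2) < tol) {
    stop("undefined circular mean: peak times are fully dispersed", call. = FALSE)
  }
  h <- ((atan2(y, x) / (2 * pi)) %% 1) * period
  if (period - h < 1e-9) h <- 0 # collapse floating-point wrap at the period
  h
}

# derive a per-participant RNG stream base seed; the large coprime strides
# keep the per-stage offsets (+1, +3) of different participants and nearby
# experiment seeds from colliding; kept below 2^31 - 1
participant_seed <- function(rng_seed, i) {
  as.integer((as.double(rng_seed) * 1009 + i * 100003) %% 2147483647)
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}
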