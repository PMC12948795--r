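#' Construct a regular 60-second epoch activity series
#'
#' An epoch series is one participant's accelerometer trace: one vector
#' magnitude per fixed-width epoch on a strictly regular timestamp grid.
#' Gaps in the input are made explicit: the constructor expands the series to
#' the full grid between the first and last timestamp and fills unobserved
#' epochs with `NA` so that downstream windows can detect missing data.
#'
#' @param timestamp `POSIXct` epoch-start times (need not be complete, must be
#'   unique and grid-aligned).
#' @param vm nonnegative vector magnitudes, one per timestamp.
#' @param participant_id identifier carried through the pipeline.
#' @param epoch_seconds epoch width in seconds (default 60).
#' @return A tibble of class `epoch_series` with columns `timestamp`, `vm` and
#'   attributes `participant_id`, `epoch_seconds`.
#' @export
epoch_series <- function(timestamp, vm, participant_id = NA_character_,
                         epoch_seconds = 60) {
  if (length(timestamp) == 0L) stop("empty epoch series", call. = FALSE)
  if (length(timestamp) != length(vm)) {
    stop("timestamp and vm lengths differ", call. = FALSE)
  }
  if (any(!is.na(vm) & vm < 0)) {
    stop("vector magnitudes must be nonnegative", call. = FALSE)
  }
  o <- order(timestamp)
  timestamp <- as.POSIXct(timestamp[o], tz = "UTC")
  vm <- as.numeric(vm[o])
  secs <- as.numeric(timestamp) - as.numeric(timestamp[1])
  if (anyDuplicated(secs)) stop("duplicate epoch timestamps", call. = FALSE)
  if (any(secs %% epoch_seconds != 0)) {
    stop("timestamps are not aligned to the epoch grid", call. = FALSE)
  }
  n <- utils::tail(secs, 1) / epoch_seconds + 1
  full <- rep(NA_real_, n)
  full[secs / epoch_seconds + 1] <- vm
  out <- tibble::tibble(
    timestamp = timestamp[1] + (seq_len(n) - 1) * epoch_seconds,
    vm = full
  )
  structure(out,
    class = c("epoch_series", class(out)),
    participant_id = participant_id,
    epoch_seconds = epoch_seconds
  )
}

# fast path for series already on a complete regular grid (simulator output);
# skips the sorting/validation work of epoch_series()
new_epoch_series <- function(timestamp, vm, participant_id, epoch_seconds) {
  out <- tibble::new_tibble(
    list(timestamp = timestamp, vm = vm),
    nrow = length(vm)
  )
  structure(out,
    class = c("epoch_series", class(out)),
    participant_id = participant_id,
    epoch_seconds = epoch_seconds
  )
}

es_epoch_seconds <- function(series) attr(series, "epoch_seconds") %||% 60
es_participant <- function(series) attr(series, "participant_id") %||% NA_character_

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> participant %s: %d epochs of %ds (%d missing)\n",
    es_participant(x), nrow(x), es_epoch_seconds(x), sum(is.na(x$vm))
  ))
  NextMethod()
}

#' Read an epoch CSV (timestamp, vector_magnitude)
#'
#' ActiLife-style exports prepend a device preamble before the header; pass
#' `skip_preamble = TRUE` to scan forward to the header line.
#'
#' @param path CSV path.
#' @param participant_id identifier to attach.
#' @param epoch_seconds epoch width in seconds.
#' @param skip_preamble skip any leading lines before the header row.
#' @return an [epoch_series()].
#' @export
read_epoch_csv <- function(path, participant_id = NA_character_,
                           epoch_seconds = 60, skip_preamble = FALSE) {
  skip <- 0L
  if (skip_preamble) {
    head_lines <- readLines(path, n = 50L)
    hit <- grep("^\\s*\"?timestamp", head_lines, ignore.case = TRUE)
    if (length(hit) == 0L) stop("no header line found in ", path, call. = FALSE)
    skip <- hit[1] - 1L
  }
  df <- readr::read_csv(path, skip = skip, col_types = readr::cols(
    timestamp = readr::col_datetime(format = ""),
    vector_magnitude = readr::col_double()
  ))
  epoch_series(df$timestamp, df$vector_magnitude,
    participant_id = participant_id, epoch_seconds = epoch_seconds
  )
}

#' Write an epoch series to CSV
#'
#' Missing epochs are omitted from the file (they are re-expanded on read).
#'
#' @param series an [epoch_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  keep <- !is.na(series$vm)
  df <- data.frame(
    timestamp = format(series$timestamp[keep], "%Y-%m-%dT%H:%M:%S"),
    vector_magnitude = series$vm[keep]
  )
  readr::write_csv(df, path)
  invisible(path)
}
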