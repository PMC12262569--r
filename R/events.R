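#' Event tables
#'
#' An event table is a data.frame with one row per event and columns
#' `onset` (seconds from run start), `duration` (seconds; 0 = impulse),
#' `amplitude` (unitless modulation, default 1) and `run` (1-based run index).
#' Additional columns (e.g. `trial_type`, `response_time`, `outcome`) are
#' carried along untouched.  Rows are kept sorted by (run, onset).
#'
#' @param onset,duration Numeric vectors in seconds; `onset >= 0`,
#'   `duration >= 0`.
#' @param amplitude Numeric modulation per event (recycled; default 1).
#' @param run Integer run index per event (recycled; default 1).
#' @param ... Further per-event columns (recycled to the number of events).
#' @return A data.frame of class `event_table`.
#' @export
event_table <- function(onset = numeric(), duration = numeric(),
                        amplitude = 1, run = 1L, ...) {
  n <- length(onset)
  if (length(duration) != n) {
    stop("`onset` and `duration` must have the same length", call. = FALSE)
  }
  if (n > 0 && (any(onset < 0) || any(duration < 0))) {
    stop("onsets and durations must be non-negative", call. = FALSE)
  }
  df <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   amplitude = rep_len(as.numeric(amplitude), n),
                   run = rep_len(as.integer(run), n))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  df <- df[order(df$run, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read a BIDS-style events TSV
#'
#' Expects at least the mandatory BIDS columns `onset`, `duration` and
#' `trial_type`; extra columns such as `response_time` and `outcome` are
#' preserved verbatim.  Onsets and durations are parsed as seconds.
#'
#' @param path Path to a tab-separated events file.
#' @param run Run index to attach to the events (default 1).
#' @return An `event_table` with `amplitude = 1` unless an `amplitude`
#'   column is present in the file.
#' @export
read_events_tsv <- function(path, run = 1L) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("n/a", "NA"))
  mandatory <- c("onset", "duration", "trial_type")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0) {
    stop(sprintf("events file '%s' is missing mandatory column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  amp <- if ("amplitude" %in% names(df)) df$amplitude else 1
  extra <- df[setdiff(names(df), c("onset", "duration", "amplitude"))]
  do.call(event_table,
          c(list(onset = df$onset, duration = df$duration, amplitude = amp,
                 run = run),
            as.list(extra)))
}

#' Write an event table as a BIDS-style events TSV
#'
#' Writes one file per call; the `run` column is dropped (BIDS stores runs in
#' separate files), every other column is written verbatim.  `write` then
#' `read` round-trips the table.
#'
#' @param table An `event_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(table, path) {
  stopifnot(is.data.frame(table))
  df <- as.data.frame(table)
  df$run <- NULL
  if (all(df$amplitude == 1)) df$amplitude <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

check_events_in_run <- function(events, grid) {
  rl <- grid$run_lengths
  if (any(events$run < 1L) || any(events$run > length(rl))) {
    stop("event run index outside the grid's runs", call. = FALSE)
  }
  ends <- events$onset + events$duration
  if (any(ends > rl[events$run] + 1e-9)) {
    stop("events extend past the end of their run", call. = FALSE)
  }
  invisible(TRUE)
}
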