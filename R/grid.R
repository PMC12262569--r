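#' Scan-time sampling grid
#'
#' Describes the acquisition grid a design matrix is sampled on: the repetition
#' time `dt`, the number of scans in each run, and the microtime oversampling
#' factor used when building regressors.  Scan n of a run is sampled at time
#' (n - 1) * dt from the run start; runs are concatenated along time.
#'
#' @param n_scans_per_run Integer vector, one entry per run.
#' @param dt Sampling interval (repetition time) in seconds; default 0.8.
#' @param oversampling Integer microtime factor (regressors are built at
#'   resolution `dt / oversampling`); default 50, fine enough that
#'   sub-20 ms timing differences survive discretisation.
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(n_scans_per_run, dt = 0.8, oversampling = 50) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  n_scans_per_run <- as.integer(n_scans_per_run)
  if (length(n_scans_per_run) < 1L || any(n_scans_per_run < 1L)) {
    stop("`n_scans_per_run` must contain at least one positive count",
         call. = FALSE)
  }
  oversampling <- as.integer(oversampling)
  if (oversampling < 1L) stop("`oversampling` must be >= 1", call. = FALSE)
  structure(
    list(dt = dt, n_scans_per_run = n_scans_per_run,
         run_lengths = n_scans_per_run * dt, oversampling = oversampling),
    class = "time_grid"
  )
}

n_runs <- function(grid) length(grid$n_scans_per_run)

total_scans <- function(grid) sum(grid$n_scans_per_run)

dt_micro <- function(grid) grid$dt / grid$oversampling

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> dt = %g s, runs = %s scans, oversampling = %d\n",
              x$dt, paste(x$n_scans_per_run, collapse = " + "),
              x$oversampling))
  invisible(x)
}
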