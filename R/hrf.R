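#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical two-gamma HRF (response peak delay 6 s, undershoot
#' delay 16 s, both dispersions 1, peak-to-undershoot ratio 6) on a regular
#' microtime grid and normalises it to unit sum over its samples.  With this
#' convention, convolving a boxcar of amplitude 1 yields a regressor whose
#' height approximates the fraction of the response mass covered by the
#' boxcar, so amplitude parameters keep the same meaning across sampling
#' rates.
#'
#' @param dt_micro Microtime sampling interval in seconds (must be > 0).
#' @param span Kernel length in seconds; at least 24 s so the undershoot is
#'   fully represented. Default 32.
#' @return An object of class `hrf_kernel`: a list with `values` (sampled
#'   kernel), `dt_micro` and `span`.
#' @examples
#' k <- canonical_hrf(0.1)
#' sum(k$values)         # 1
#' which.max(k$values)   # peak near 5 s
#' @export
canonical_hrf <- function(dt_micro, span = 32) {
  if (!is.numeric(dt_micro) || length(dt_micro) != 1L || !is.finite(dt_micro) ||
      dt_micro <= 0) {
    stop("`dt_micro` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(span) || length(span) != 1L || span < 24) {
    stop("`span` must be a single number >= 24 seconds", call. = FALSE)
  }
  n <- floor(span / dt_micro)
  t <- (seq_len(n) - 1) * dt_micro
  # difference of gamma densities: shape 6 and 16, rate 1, ratio 1:6
  v <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  v <- v / sum(v)
  structure(list(values = v, dt_micro = dt_micro, span = span),
            class = "hrf_kernel")
}

#' Temporal derivative of an HRF kernel
#'
#' First-order forward finite difference of the kernel on its own microtime
#' grid, left un-normalised: only its column space matters for collinearity
#' analyses and for absorbing small onset shifts.
#'
#' @param base An `hrf_kernel`, usually from [canonical_hrf()].
#' @return An `hrf_kernel` of the same length whose samples sum to
#'   approximately zero.
#' @export
temporal_derivative_kernel <- function(base) {
  stopifnot(inherits(base, "hrf_kernel"))
  v <- base$values
  dv <- c(diff(v), 0) / base$dt_micro
  structure(list(values = dv, dt_micro = base$dt_micro, span = base$span),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %d samples, dt = %g s, span = %g s, sum = %.3g\n",
              length(x$values), x$dt_micro, x$span, sum(x$values)))
  invisible(x)
}
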