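# FFT convolution of each column of M (n x p) with `kernel`, truncated to the
# first n samples (causal part). Used at microtime resolution.
convolve_cols <- function(M, kernel) {
  n <- nrow(M)
  m <- length(kernel)
  L <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  K <- stats::fft(c(kernel, rep(0, L - m)))
  Mp <- rbind(M, matrix(0, L - n, ncol(M)))
  FM <- stats::mvfft(Mp)
  out <- Re(stats::mvfft(FM * K, inverse = TRUE)) / L
  out[seq_len(n), , drop = FALSE]
}

# Microtime neural signal for one run. Half-open boxcars [onset, onset+dur);
# impulses carry unit mass (bin value amplitude / dt_micro) so their scale is
# commensurate with boxcars as duration -> 0.
neural_signal <- function(events, n_micro, dtm, shape) {
  x <- numeric(n_micro)
  if (nrow(events) == 0) return(x)
  if (shape == "impulse") {
    i <- pmin(floor(events$onset / dtm) + 1L, n_micro)
    for (k in seq_along(i)) x[i[k]] <- x[i[k]] + events$amplitude[k] / dtm
  } else {
    i0 <- floor(events$onset / dtm) + 1L
    i1 <- floor((events$onset + events$duration) / dtm)  # last bin inside
    for (k in seq_along(i0)) {
      if (i1[k] >= i0[k]) {
        idx <- i0[k]:min(i1[k], n_micro)
        x[idx] <- x[idx] + events$amplitude[k]
      }
    }
  }
  x
}

#' Build an HRF-convolved regressor from events
#'
#' The neural signal is built at microtime resolution (`grid$dt /
#' grid$oversampling`), convolved with the kernel, and sampled at scan onsets.
#' `shape = "boxcar"` uses amplitude over the half-open interval
#' \[onset, onset + duration); `shape = "impulse"` places unit mass at the
#' onset and ignores durations.  With `with_derivative = TRUE` a second column
#' convolved with the temporal-derivative kernel is appended.
#'
#' @param events An `event_table` (may span several runs).
#' @param grid A [time_grid()].
#' @param shape `"boxcar"` or `"impulse"`.
#' @param kernel An `hrf_kernel`; default `canonical_hrf(dt_micro(grid))`.
#' @param with_derivative Append the temporal-derivative regressor?
#' @return A numeric matrix with `sum(grid$n_scans_per_run)` rows and one or
#'   two columns (`"x"`, and `"x_derivative"` when requested), runs
#'   concatenated along time.
#' @export
make_regressor <- function(events, grid, shape = c("boxcar", "impulse"),
                           kernel = NULL, with_derivative = FALSE) {
  shape <- match.arg(shape)
  stopifnot(inherits(grid, "time_grid"))
  check_events_in_run(events, grid)
  dtm <- dt_micro(grid)
  if (is.null(kernel)) kernel <- canonical_hrf(dtm)
  stopifnot(inherits(kernel, "hrf_kernel"))
  if (abs(kernel$dt_micro - dtm) > 1e-12) {
    stop("kernel sampling interval does not match the grid's microtime",
         call. = FALSE)
  }
  kernels <- list(kernel$values)
  if (with_derivative) {
    kernels <- c(kernels, list(temporal_derivative_kernel(kernel)$values))
  }
  os <- grid$oversampling
  out <- vector("list", n_runs(grid))
  for (r in seq_len(n_runs(grid))) {
    nr <- grid$n_scans_per_run[r]
    n_micro <- nr * os
    ev <- events[events$run == r, , drop = FALSE]
    x <- neural_signal(ev, n_micro, dtm, shape)
    idx <- (seq_len(nr) - 1L) * os + 1L
    if (all(x == 0)) {
      out[[r]] <- matrix(0, nr, length(kernels))
    } else {
      conv <- convolve_cols(matrix(rep(x, length(kernels)), ncol = length(kernels)),
                            kernels[[1L]])
      # derivative column uses its own kernel
      if (length(kernels) == 2L) {
        conv[, 2L] <- convolve_cols(matrix(x, ncol = 1L), kernels[[2L]])[, 1L]
      }
      out[[r]] <- conv[idx, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  colnames(res) <- if (with_derivative) c("x", "x_derivative") else "x"
  res
}

#' Discrete-cosine high-pass drift basis
#'
#' Per-run DCT-II basis with `K = floor(2 * T / cutoff)` columns (run length
#' `T` seconds), unit-normalised; the standard high-pass drift model with a
#' 128 s cutoff retains fluctuations slower than the cutoff period.
#' Runs are stacked block-diagonally so each run gets its own drift block.
#'
#' @param grid A [time_grid()].
#' @param cutoff High-pass cutoff period in seconds (default 128).
#' @return Matrix with `sum(n_scans_per_run)` rows; zero columns if the cutoff
#'   exceeds twice every run length.  Column names `drift_r<run>_<k>`.
#' @export
cosine_drift_basis <- function(grid, cutoff = 128) {
  stopifnot(inherits(grid, "time_grid"))
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  blocks <- list()
  nm <- character()
  ntot <- total_scans(grid)
  offset <- 0L
  for (r in seq_len(n_runs(grid))) {
    N <- grid$n_scans_per_run[r]
    Tlen <- grid$run_lengths[r]
    K <- floor(2 * Tlen / cutoff)
    if (K > 0) {
      n <- seq_len(N) - 1L
      B <- matrix(0, ntot, K)
      for (k in seq_len(K)) {
        col <- cos(pi * k * (2 * n + 1) / (2 * N)) * sqrt(2 / N)
        B[offset + seq_len(N), k] <- col
      }
      blocks[[length(blocks) + 1L]] <- B
      nm <- c(nm, sprintf("drift_r%d_%d", r, seq_len(K)))
    }
    offset <- offset + N
  }
  if (length(blocks) == 0) {
    out <- matrix(0, ntot, 0)
  } else {
    out <- do.call(cbind, blocks)
    colnames(out) <- nm
  }
  out
}
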