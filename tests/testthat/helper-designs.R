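# Shared fixtures, all generated in code.

# A toy design on an integer grid: intercept + named plain columns
toy_design <- function(cols, dt = 1) {
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  grid <- time_grid(nrow(X), dt = dt, oversampling = 1)
  assemble_design(as.list(as.data.frame(X)), grid)
}

# Two overlapping condition regressors on a ~50 s run (adjacent boxcars),
# the canonical collinearity scenario used across the diagnostics tests.
overlapping_pair <- function(duration = 2.5, spacing = 5, n_scans = 63) {
  grid <- time_grid(n_scans, dt = 0.8, oversampling = 50)
  onsets <- seq(0, by = spacing, length.out = 10)
  A <- make_regressor(event_table(onset = onsets,
                                  duration = rep(duration, 10)),
                      grid, "boxcar")
  B <- make_regressor(event_table(onset = onsets + duration,
                                  duration = rep(duration, 10)),
                      grid, "boxcar")
  list(grid = grid, A = drop(A), B = drop(B))
}

# 3-D Gaussian noise smoothed with a separable [1,2,1]/4 kernel; smoothing
# preserves the null (zero mean) while giving cluster-extent inference the
# spatial coherence it is designed for.
smooth_noise_map <- function(dims, passes = 2) {
  a <- array(stats::rnorm(prod(dims)), dims)
  k <- c(1, 2, 1) / 4
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      a <- apply(a, setdiff(1:3, ax), function(v) {
        n <- length(v)
        vv <- c(v[1], v, v[n])
        k[1] * vv[1:n] + k[2] * vv[2:(n + 1)] + k[3] * vv[3:(n + 2)]
      })
      a <- aperm(a, order(c(ax, setdiff(1:3, ax))))
    }
  }
  a
}

# Cached small fleet of emulated subjects for the simulation tests (built
# once per test run; ~40 s of work shared across files).
.sim_cache <- new.env(parent = emptyenv())

get_sim_schedules <- function(n = 40, seed_base = 9000) {
  key <- sprintf("sched_%d_%d", n, seed_base)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- lapply(seq_len(n), function(s) {
      generate_mid_schedule(seed = seed_base + s)
    })
  }
  .sim_cache[[key]]
}
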