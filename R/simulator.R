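#' Variance components of the mixed-effects simulation
#'
#' @param sigma_w Within-subject noise SD (scan-to-scan Gaussian noise);
#'   default 1.
#' @param sigma_b Between-subject SD of the true amplitudes; default 1.5.
#' @return A list of class `variance_components`.
#' @export
variance_components <- function(sigma_w = 1, sigma_b = 1.5) {
  if (sigma_w <= 0 || sigma_b < 0) {
    stop("`sigma_w` must be > 0 and `sigma_b` >= 0", call. = FALSE)
  }
  structure(list(sigma_w = sigma_w, sigma_b = sigma_b),
            class = "variance_components")
}

#' Built-in simulation scenarios
#'
#' Each scenario names the true mean amplitudes of the saturated-model
#' parameters; every unlisted parameter has mean 0 (all parameters still get
#' between-subject variability).  The built-ins are the settings used to
#' calibrate ~80% group-level power at 500 subjects: `null` (all zero),
#' `cue_win` (Cue LargeWin = Cue SmallWin = 0.22), `fixation_win`
#' (Fix LargeWin = Fix SmallWin = 0.22), `probe_win` (Probe Win = 0.85),
#' `rt` (RT = 0.35) and `feedback` (FB LargeWin Hit = FB LargeWin Miss =
#' 0.25).
#'
#' @param names Which scenarios to return (default all six).
#' @return Named list of scenarios; each a named numeric vector of nonzero
#'   mean amplitudes.
#' @export
sim_scenarios <- function(names = c("null", "cue_win", "fixation_win",
                                    "probe_win", "rt", "feedback")) {
  all <- list(
    null = stats::setNames(numeric(0), character(0)),
    cue_win = c(Cue_LargeWin = 0.22, Cue_SmallWin = 0.22),
    fixation_win = c(Fix_LargeWin = 0.22, Fix_SmallWin = 0.22),
    probe_win = c(Probe_Win = 0.85),
    rt = c(RT = 0.35),
    feedback = c(FB_LargeWin_Hit = 0.25, FB_LargeWin_Miss = 0.25)
  )
  unknown <- setdiff(names, names(all))
  if (length(unknown) > 0) {
    stop(sprintf("unknown scenario(s): %s; built-ins are %s",
                 paste(unknown, collapse = ", "),
                 paste(names(all), collapse = ", ")), call. = FALSE)
  }
  all[names]
}

#' Simulation configuration
#'
#' @param n_subjects Subjects per dataset (default 500).
#' @param n_datasets Simulated datasets (default 1000).
#' @param alpha Two-sided group test level (default 0.05).
#' @param seed Integer seed for the whole grid.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 500L, n_datasets = 1000L, alpha = 0.05,
                       seed = 1L) {
  if (n_subjects < 2 || n_datasets < 1) {
    stop("`n_subjects` must be >= 2 and `n_datasets` >= 1", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_datasets = as.integer(n_datasets),
                 alpha = alpha, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw per-subject true amplitudes
#'
#' Every parameter named in `param_names` is drawn independently per subject
#' from Normal(scenario mean, `sigma_b^2`); parameters not named in the
#' scenario have mean 0.
#'
#' @param scenario Named numeric vector of mean amplitudes (see
#'   [sim_scenarios()]).
#' @param vc A [variance_components()] object.
#' @param n_subjects Number of subjects.
#' @param param_names Saturated-model parameter names.
#' @return Matrix `length(param_names) x n_subjects`.
#' @export
draw_subject_betas <- function(scenario, vc, n_subjects, param_names) {
  unknown <- setdiff(names(scenario), param_names)
  if (length(unknown) > 0) {
    stop(sprintf("scenario names not in the model: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  mu <- stats::setNames(numeric(length(param_names)), param_names)
  mu[names(scenario)] <- scenario
  p <- length(param_names)
  mu + vc$sigma_b * matrix(stats::rnorm(p * n_subjects), p, n_subjects,
                           dimnames = list(param_names, NULL))
}

#' Simulate a voxel time series from a design and true amplitudes
#'
#' `Y = X_task beta + epsilon` with i.i.d. Gaussian noise of SD
#' `vc$sigma_w`; only the task columns carry signal.
#'
#' @param design A `design_matrix` (the generating, saturated design).
#' @param betas Numeric vector (one subject) or matrix `p_task x n` (columns
#'   are independent realisations) aligned to the design's task columns.
#' @param vc A [variance_components()] object.
#' @return Numeric vector or `n_scans x n` matrix.
#' @export
simulate_timeseries <- function(design, betas, vc = variance_components()) {
  Xt <- design$values[, design$task_cols, drop = FALSE]
  b <- if (is.null(dim(betas))) matrix(betas, ncol = 1L) else betas
  if (nrow(b) != ncol(Xt)) {
    stop(sprintf("betas have %d rows but the design has %d task columns",
                 nrow(b), ncol(Xt)), call. = FALSE)
  }
  Y <- Xt %*% b + vc$sigma_w * matrix(stats::rnorm(nrow(Xt) * ncol(b)),
                                      nrow(Xt), ncol(b))
  if (is.null(dim(betas))) drop(Y) else Y
}

#' Ordinary least squares contrast estimates
#'
#' Fits `Y = X beta + e` by OLS and returns `c beta-hat` for each contrast.
#' Contrasts weight canonical task columns only; derivative and nuisance
#' columns are estimated but never contrasted.
#'
#' @param design The fitting `design_matrix` (full column rank).
#' @param Y Numeric vector or `n_scans x n` matrix of time series.
#' @param contrasts Named list of contrasts (see [efficiency()]).
#' @return Matrix `length(contrasts) x n` of contrast estimates.
#' @export
fit_contrasts <- function(design, Y, contrasts) {
  X <- design$values
  check_full_rank(X)
  C <- t(vapply(contrasts, function(cs) align_contrast(design, cs),
                numeric(ncol(X))))
  Ym <- if (is.null(dim(Y))) matrix(Y, ncol = 1L) else Y
  bhat <- qr.coef(qr(X), Ym)
  est <- C %*% bhat
  rownames(est) <- names(contrasts)
  est
}

#' Mixed-effects variance decomposition of a contrast
#'
#' `within = c (X'X)^-1 c' * sigma_w^2`, `between = c c' * sigma_b^2`,
#' `total = within + between`, and `sd_ratio = sqrt(total / within)` - the
#' factor by which the total first-level contrast SD exceeds the purely
#' within-subject SD.
#'
#' @inheritParams efficiency
#' @param vc A [variance_components()] object.
#' @return A list of class `mixed_variance` with fields `within`, `between`,
#'   `total`, `sd_ratio`.
#' @export
mixed_variance <- function(design, contrast, vc = variance_components()) {
  cc <- align_contrast(design, contrast)
  XtX <- check_full_rank(design$values)
  within <- drop(crossprod(cc, solve(XtX, cc))) * vc$sigma_w^2
  between <- sum(cc^2) * vc$sigma_b^2
  structure(list(within = within, between = between,
                 total = within + between,
                 sd_ratio = sqrt((within + between) / within)),
            class = "mixed_variance")
}

# map contrasts defined on saturated parameter names to a "true value" under
# a scenario, and decide whether the cell carries signal
contrast_truth <- function(contrast, scenario) {
  nz <- contrast[contrast != 0]
  involved <- names(nz)[names(nz) %in% names(scenario)]
  value <- sum(nz[involved] * scenario[involved])
  list(value = value,
       signal = any(names(nz) %in% names(scenario)[scenario != 0]))
}

#' Run the bias / type-I-error / power simulation grid
#'
#' For each scenario and each simulated dataset, draws per-subject true
#' amplitudes on the saturated parameters, simulates every subject's time
#' series from that subject's saturated design, fits each candidate model by
#' OLS, and performs a one-sample two-sided t-test of every contrast across
#' subjects.  Summaries per (scenario, model, contrast): the mean estimate
#' over datasets, the average group t-statistic of the bias (mean estimate
#' minus true contrast value; `|t| > 1.96` on average flags significant
#' bias), the rejection rate at `config$alpha`, and - for cells whose true
#' contrast value is null - an exact binomial test of the rejection count
#' against `alpha` (`inflated` flag at level 0.05).  Cells where the contrast
#' involves a parameter with nonzero true mean are marked `signal` and their
#' rejection rate is power, not error rate.  Subject schedules (and hence
#' designs) are generated once and reused across datasets.
#'
#' @param scenarios Named list from [sim_scenarios()] (subset allowed).
#' @param models Character vector of fitting models, from `"saturated"`,
#'   `"cuefeedback"` (truth is always generated from the saturated design).
#' @param schedules List of [generate_mid_schedule()] schedules, one per
#'   subject (length `config$n_subjects`), or `NULL` to generate them from
#'   `config$seed`.
#' @param config A [sim_config()].
#' @param vc A [variance_components()].
#' @param oversampling Microtime factor for the designs.
#' @return A data.frame of class `sim_summary` with columns `scenario`,
#'   `model`, `contrast`, `true_value`, `signal`, `mean_estimate`, `bias_t`,
#'   `rejection_rate`, `inflated`.
#' @export
run_scenarios <- function(scenarios = sim_scenarios(),
                          models = c("cuefeedback", "saturated"),
                          schedules = NULL, config = sim_config(),
                          vc = variance_components(), oversampling = 50) {
  models <- match.arg(models, c("cuefeedback", "saturated"),
                      several.ok = TRUE)
  set.seed(config$seed)
  n_sub <- config$n_subjects
  if (is.null(schedules)) {
    schedules <- lapply(seq_len(n_sub), function(s) {
      generate_mid_schedule(seed = NULL)
    })
  }
  if (length(schedules) != n_sub) {
    stop("need one schedule per subject", call. = FALSE)
  }
  designs_sat <- lapply(schedules, mid_design, model = "saturated",
                        oversampling = oversampling)
  param_names <- task_column_names(designs_sat[[1]])
  fit_designs <- list()
  for (m in models) {
    fit_designs[[m]] <- if (m == "saturated") {
      designs_sat
    } else {
      lapply(schedules, mid_design, model = m, oversampling = oversampling)
    }
  }
  # per subject: X_task of the generating design, and C %*% pinv per model
  Xt_list <- lapply(designs_sat, function(d) {
    d$values[, d$task_cols, drop = FALSE]
  })
  contrasts <- contrast_library(param_names)
  n_con <- length(contrasts)
  proj <- lapply(models, function(m) {
    cn <- fit_designs[[m]][[1]]$column_names
    con_m <- contrast_library(cn)
    lapply(fit_designs[[m]], function(d) {
      X <- d$values
      C <- t(vapply(con_m, function(cs) as.numeric(cs), numeric(ncol(X))))
      C %*% solve(crossprod(X), t(X))  # n_con x n_scans
    })
  })
  names(proj) <- models
  D <- config$n_datasets
  crit <- stats::qt(1 - config$alpha / 2, df = n_sub - 1L)
  rows <- list()
  for (sc_name in names(scenarios)) {
    scenario <- scenarios[[sc_name]]
    sums <- sqs <- lapply(models, function(m) matrix(0, n_con, D))
    names(sums) <- names(sqs) <- models
    for (s in seq_len(n_sub)) {
      B <- draw_subject_betas(scenario, vc, D, param_names)
      Y <- Xt_list[[s]] %*% B +
        vc$sigma_w * matrix(stats::rnorm(nrow(Xt_list[[s]]) * D),
                            nrow(Xt_list[[s]]), D)
      for (m in models) {
        est <- proj[[m]][[s]] %*% Y  # n_con x D
        sums[[m]] <- sums[[m]] + est
        sqs[[m]] <- sqs[[m]] + est^2
      }
    }
    truths <- lapply(contrasts, function(cs) {
      contrast_truth(cs[cs != 0], scenario)
    })
    for (m in models) {
      mean_s <- sums[[m]] / n_sub
      sd_s <- sqrt(pmax(sqs[[m]] - n_sub * mean_s^2, 0) / (n_sub - 1L))
      se_s <- sd_s / sqrt(n_sub)
      t0 <- mean_s / se_s            # test vs 0, per dataset
      for (k in seq_len(n_con)) {
        tr <- truths[[k]]
        t_bias <- (mean_s[k, ] - tr$value) / se_s[k, ]
        rej <- mean(abs(t0[k, ]) > crit)
        inflated <- NA
        if (!tr$signal) {
          bt <- stats::binom.test(sum(abs(t0[k, ]) > crit), D,
                                  p = config$alpha)
          inflated <- bt$p.value < 0.05 && rej > config$alpha
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc_name, model = m, contrast = names(contrasts)[k],
          true_value = tr$value, signal = tr$signal,
          mean_estimate = mean(mean_s[k, ]), bias_t = mean(t_bias),
          rejection_rate = rej, inflated = inflated,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "vc") <- vc
  class(out) <- c("sim_summary", "data.frame")
  out
}
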