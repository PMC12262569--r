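CUE_TYPES <- c("LargeWin", "SmallWin", "Neutral", "SmallLoss", "LargeLoss")
OUTCOMES <- c("Hit", "TooSlow", "TooSoon")

#' Parameters of the MID schedule emulator
#'
#' Timing ranges and outcome structure of the Monetary Incentive Delay trial
#' as administered in the large multi-site developmental protocol the
#' emulator reproduces: per trial, Cue (1.781-2.039 s), Fixation
#' (1.500-3.666 s), Probe (0.172-0.497 s) and Feedback (1.473-1.789 s) follow
#' each other with no gaps and no inter-trial interval; the feedback screen
#' lasts 1.950 s minus the trial's probe duration.  Outcomes are ~57% Hit,
#' 36% Too Slow, 7% Too Soon, and durations differ systematically by outcome:
#' in expectation Hit probes are ~30 ms longer, Hit fixations ~112 ms longer,
#' and Miss response times ~89 ms longer (shift defaults are the midpoints of
#' the reported 26-33 / 63-160 / 78-100 ms ranges), all clipped to the legal
#' ranges.
#'
#' @param cue_range,fixation_range,probe_range,feedback_range,rt_range
#'   Two-element numeric ranges in seconds.
#' @param outcome_probs Named probabilities for Hit / TooSlow / TooSoon.
#' @param probe_hit_shift,fixation_hit_shift Expected Hit-minus-Miss duration
#'   differences in seconds (applied half up for Hits, half down for Misses).
#' @param rt_miss_shift Expected Miss-minus-Hit RT difference in seconds.
#' @param feedback_total Feedback duration is `feedback_total - probe
#'   duration`, clipped to `feedback_range`.
#' @param rt_toosoon_prob Probability that a Too Soon trial has a recorded RT
#'   (an RT is only logged when an extra press follows the probe onset).
#' @return A list of class `mid_params`.
#' @export
mid_params <- function(cue_range = c(1.781, 2.039),
                       fixation_range = c(1.500, 3.666),
                       probe_range = c(0.172, 0.497),
                       feedback_range = c(1.473, 1.789),
                       rt_range = c(0.105, 1.581),
                       outcome_probs = c(Hit = 0.57, TooSlow = 0.36,
                                         TooSoon = 0.07),
                       probe_hit_shift = 0.030,
                       fixation_hit_shift = 0.112,
                       rt_miss_shift = 0.089,
                       feedback_total = 1.950,
                       rt_toosoon_prob = 0.5) {
  p <- list(cue_range = cue_range, fixation_range = fixation_range,
            probe_range = probe_range, feedback_range = feedback_range,
            rt_range = rt_range, outcome_probs = outcome_probs,
            probe_hit_shift = probe_hit_shift,
            fixation_hit_shift = fixation_hit_shift,
            rt_miss_shift = rt_miss_shift, feedback_total = feedback_total,
            rt_toosoon_prob = rt_toosoon_prob)
  for (nm in c("cue_range", "fixation_range", "probe_range",
               "feedback_range", "rt_range")) {
    r <- p[[nm]]
    if (length(r) != 2L || r[1] <= 0 || r[2] < r[1]) {
      stop(sprintf("`%s` must be an increasing positive range", nm),
           call. = FALSE)
    }
  }
  if (abs(sum(outcome_probs) - 1) > 1e-8 || any(outcome_probs < 0) ||
      !setequal(names(outcome_probs), OUTCOMES)) {
    stop("`outcome_probs` must be probabilities over Hit/TooSlow/TooSoon",
         call. = FALSE)
  }
  if (probe_hit_shift / 2 >= diff(probe_range) ||
      fixation_hit_shift / 2 >= diff(fixation_range) ||
      rt_miss_shift / 2 >= diff(rt_range)) {
    stop("outcome shifts exceed the corresponding duration ranges",
         call. = FALSE)
  }
  if (feedback_total - probe_range[1] < feedback_range[1]) {
    stop("`feedback_total` is infeasible given the probe and feedback ranges",
         call. = FALSE)
  }
  class(p) <- "mid_params"
  p
}

clip <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Generate a synthetic MID trial schedule
#'
#' Emulates the trial structure described in [mid_params()]: `n_runs` runs of
#' `trials_per_run` sequential trials (`trials_per_run / 5` per cue type,
#' uniformly permuted within run), components abutting with no gaps, outcomes
#' drawn i.i.d. with the configured probabilities, and outcome-conditional
#' duration shifts.  Each schedule is guaranteed to contain at least one Hit
#' and one Miss per cue type so that feedback regressors split by cue type and
#' outcome are never empty.  The run length is the last feedback offset
#' rounded up to a whole number of `dt`-second scans.
#'
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param params A [mid_params()] object.
#' @param n_runs,trials_per_run Schedule size (defaults 2 and 50;
#'   `trials_per_run` must be a multiple of 5).
#' @param dt Scan sampling interval used to round run lengths (default 0.8 s).
#' @return A data.frame of class `mid_schedule` with per-trial columns `run`,
#'   `trial`, `cue_type`, `outcome`, `cue_onset`, `cue_duration`,
#'   `fixation_duration`, `probe_duration`, `feedback_duration`,
#'   `response_time` (NA when unrecorded), and attributes `n_scans_per_run`,
#'   `dt`, `params`, `seed`.
#' @export
generate_mid_schedule <- function(seed = NULL, params = mid_params(),
                                  n_runs = 2L, trials_per_run = 50L,
                                  dt = 0.8) {
  stopifnot(inherits(params, "mid_params"))
  if (trials_per_run %% length(CUE_TYPES) != 0) {
    stop("`trials_per_run` must be a multiple of the 5 cue types",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  per_type <- trials_per_run %/% length(CUE_TYPES)
  runs <- vector("list", n_runs)
  n_total <- n_runs * trials_per_run
  # outcomes drawn jointly, redrawn in the rare case a cue type lacks a Hit
  # or a Miss anywhere in the schedule (keeps feedback cells non-empty)
  cue <- unlist(lapply(seq_len(n_runs), function(r) {
    sample(rep(CUE_TYPES, per_type))
  }))
  repeat {
    outcome <- sample(OUTCOMES, n_total, replace = TRUE,
                      prob = params$outcome_probs[OUTCOMES])
    hit <- outcome == "Hit"
    ok <- all(vapply(CUE_TYPES, function(ct) {
      any(hit[cue == ct]) && any(!hit[cue == ct])
    }, logical(1)))
    if (ok) break
  }
  runif_range <- function(n, r) stats::runif(n, r[1], r[2])
  sgn <- ifelse(hit, 0.5, -0.5)
  cue_dur <- runif_range(n_total, params$cue_range)
  fix_dur <- clip(runif_range(n_total, params$fixation_range) +
                    sgn * params$fixation_hit_shift, params$fixation_range)
  probe_dur <- clip(runif_range(n_total, params$probe_range) +
                      sgn * params$probe_hit_shift, params$probe_range)
  fb_dur <- clip(params$feedback_total - probe_dur, params$feedback_range)
  rt <- clip(runif_range(n_total, params$rt_range) -
               sgn * params$rt_miss_shift, params$rt_range)
  has_rt <- ifelse(outcome == "TooSoon",
                   stats::runif(n_total) < params$rt_toosoon_prob, TRUE)
  rt[!has_rt] <- NA_real_
  run <- rep(seq_len(n_runs), each = trials_per_run)
  trial <- rep(seq_len(trials_per_run), n_runs)
  trial_len <- cue_dur + fix_dur + probe_dur + fb_dur
  cue_onset <- numeric(n_total)
  for (r in seq_len(n_runs)) {
    i <- which(run == r)
    cue_onset[i] <- cumsum(c(0, trial_len[i][-length(i)]))
  }
  sched <- data.frame(run = run, trial = trial, cue_type = cue,
                      outcome = outcome, cue_onset = cue_onset,
                      cue_duration = cue_dur, fixation_duration = fix_dur,
                      probe_duration = probe_dur, feedback_duration = fb_dur,
                      response_time = rt, stringsAsFactors = FALSE)
  run_end <- vapply(seq_len(n_runs), function(r) {
    i <- run == r
    max(cue_onset[i] + trial_len[i])
  }, numeric(1))
  attr(sched, "n_scans_per_run") <- as.integer(ceiling(run_end / dt))
  attr(sched, "dt") <- dt
  attr(sched, "params") <- params
  attr(sched, "seed") <- seed
  class(sched) <- c("mid_schedule", "data.frame")
  sched
}

#' Adaptive probe-duration staircase
#'
#' The protocol targets 60% accuracy by adjusting the probe duration every
#' third trial based on accuracy over the last six trials (across all cue
#' conditions): above target the probe gets harder (shorter), otherwise
#' easier (longer), clipped to the legal probe range.  The i.i.d. outcome
#' draws of [generate_mid_schedule()] are the default for simulation; the
#' staircase is provided for behaviourally realistic schedules.
#'
#' @param accuracy_history Logical/0-1 vector of trial accuracies so far.
#' @param current Current probe duration in seconds.
#' @param target Target accuracy (default 0.6).
#' @param step Adjustment step in seconds (default 0.015).
#' @param probe_range Legal probe duration range.
#' @return The probe duration for the next trial.
#' @export
staircase_probe_duration <- function(accuracy_history, current,
                                     target = 0.6, step = 0.015,
                                     probe_range = c(0.172, 0.497)) {
  n <- length(accuracy_history)
  if (n == 0 || n %% 3L != 0) return(clip(current, probe_range))
  recent <- utils::tail(accuracy_history, 6L)
  acc <- mean(recent)
  out <- if (acc > target) current - step else current + step
  clip(out, probe_range)
}

#' @export
print.mid_schedule <- function(x, ...) {
  cat(sprintf("<mid_schedule> %d runs x %d trials, %s scans of %g s\n",
              length(unique(x$run)), sum(x$run == x$run[1]),
              paste(attr(x, "n_scans_per_run"), collapse = " + "),
              attr(x, "dt")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
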