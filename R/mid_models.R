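#' Built-in time series model specifications for the MID task
#'
#' * `"cuefeedback"` mirrors the consortium model: impulse regressors at event
#'   onsets for the 5 Cue types and the 10 Feedback cells (cue type x
#'   Hit/Miss), each paired with its temporal derivative - 30 task columns.
#' * `"saturated"` models every trial component with duration-matched
#'   boxcars: 5 Cue + 5 Fixation (by cue type) + 3 Probe (Win/Loss/Neutral) +
#'   1 response-time regressor (probe onset, RT as duration) + 10 Feedback -
#'   24 task columns, no derivatives.
#' * `"saturated_derivs"` adds a temporal derivative to every saturated
#'   regressor (48 task columns; 49 parameters with the intercept).
#'
#' @param name One of `"cuefeedback"`, `"saturated"`, `"saturated_derivs"`.
#' @return A list of class `model_spec` mapping event components to
#'   `(shape, split, derivative)`.
#' @export
model_spec <- function(name = c("cuefeedback", "saturated",
                                "saturated_derivs")) {
  name <- match.arg(name)
  comp <- function(shape, split, derivative) {
    list(shape = shape, split = split, derivative = derivative)
  }
  spec <- switch(name,
    cuefeedback = list(
      cue = comp("impulse", "cue_type", TRUE),
      feedback = comp("impulse", "cue_outcome", TRUE)
    ),
    saturated = list(
      cue = comp("boxcar", "cue_type", FALSE),
      fixation = comp("boxcar", "cue_type", FALSE),
      probe = comp("boxcar", "valence", FALSE),
      rt = comp("boxcar", "none", FALSE),
      feedback = comp("boxcar", "cue_outcome", FALSE)
    ),
    saturated_derivs = list(
      cue = comp("boxcar", "cue_type", TRUE),
      fixation = comp("boxcar", "cue_type", TRUE),
      probe = comp("boxcar", "valence", TRUE),
      rt = comp("boxcar", "none", TRUE),
      feedback = comp("boxcar", "cue_outcome", TRUE)
    ))
  structure(spec, name = name, class = "model_spec")
}

valence_of <- function(cue_type) {
  ifelse(cue_type %in% c("LargeWin", "SmallWin"), "Win",
         ifelse(cue_type %in% c("LargeLoss", "SmallLoss"), "Loss", "Neutral"))
}

component_prefix <- c(cue = "Cue", fixation = "Fix", probe = "Probe",
                      rt = "RT", feedback = "FB")

# onset/duration of one component for every trial of the schedule
component_timing <- function(schedule, component) {
  on <- schedule$cue_onset
  cd <- schedule$cue_duration
  fd <- schedule$fixation_duration
  pd <- schedule$probe_duration
  switch(component,
    cue = list(onset = on, duration = cd),
    fixation = list(onset = on + cd, duration = fd),
    probe = list(onset = on + cd + fd, duration = pd),
    rt = list(onset = on + cd + fd, duration = schedule$response_time),
    feedback = list(onset = on + cd + fd + pd,
                    duration = schedule$feedback_duration),
    stop(sprintf("unknown component '%s'", component), call. = FALSE))
}

#' Expand a schedule into per-regressor event tables
#'
#' Splits each model component of `spec` over the schedule's trials: Feedback
#' is split by cue type x Hit/Miss (Miss = Too Slow or Too Soon), the probe
#' split for the saturated model is Win/Loss/Neutral, and the RT regressor
#' only receives events from trials with a recorded response time.
#'
#' @param schedule A [generate_mid_schedule()] result.
#' @param spec A [model_spec()].
#' @return Named list of [event_table()]s, one per regressor, in the model's
#'   canonical column order.
#' @export
schedule_to_events <- function(schedule, spec) {
  stopifnot(inherits(schedule, "mid_schedule"), inherits(spec, "model_spec"))
  out <- list()
  for (component in names(spec)) {
    cs <- spec[[component]]
    tm <- component_timing(schedule, component)
    keep <- rep(TRUE, nrow(schedule))
    if (component == "rt") keep <- !is.na(schedule$response_time)
    label <- switch(cs$split,
      cue_type = schedule$cue_type,
      valence = valence_of(schedule$cue_type),
      cue_outcome = paste(schedule$cue_type,
                          ifelse(schedule$outcome == "Hit", "Hit", "Miss"),
                          sep = "_"),
      none = rep("", nrow(schedule)),
      stop(sprintf("unknown split '%s' in model spec", cs$split),
           call. = FALSE))
    levels <- switch(cs$split,
      cue_type = CUE_TYPES,
      valence = c("Win", "Loss", "Neutral"),
      cue_outcome = as.vector(t(outer(CUE_TYPES, c("Hit", "Miss"),
                                      paste, sep = "_"))),
      none = "")
    for (lv in levels) {
      i <- keep & label == lv
      nm <- component_prefix[[component]]
      if (nzchar(lv)) nm <- paste(nm, lv, sep = "_")
      out[[nm]] <- event_table(onset = tm$onset[i],
                               duration = tm$duration[i],
                               run = schedule$run[i])
    }
  }
  out
}

#' Build a first-level design matrix for an emulated MID schedule
#'
#' Convenience wrapper: expands the schedule with [schedule_to_events()],
#' convolves every regressor with the canonical HRF (plus derivatives where
#' the model asks for them), concatenates the runs, and appends an optional
#' drift block and a single intercept.
#'
#' @param schedule A [generate_mid_schedule()] result.
#' @param model A [model_spec()] or its name.
#' @param oversampling Microtime factor (default 50).
#' @param drift_cutoff If non-`NULL`, add a per-run cosine drift basis with
#'   this cutoff (seconds).  Simulation-style designs use `NULL`.
#' @param intercept Add an intercept column (default `TRUE`).
#' @return A `design_matrix`.
#' @export
mid_design <- function(schedule, model = "saturated", oversampling = 50,
                       drift_cutoff = NULL, intercept = TRUE) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "model_spec"))
  grid <- time_grid(attr(schedule, "n_scans_per_run"),
                    dt = attr(schedule, "dt"), oversampling = oversampling)
  events <- schedule_to_events(schedule, model)
  shapes <- derivs <- stats::setNames(character(0), character(0))
  specs <- list()
  for (component in names(model)) {
    pre <- component_prefix[[component]]
    for (nm in names(events)) {
      if (nm == pre || startsWith(nm, paste0(pre, "_"))) {
        specs[[nm]] <- list(events = events[[nm]],
                            shape = model[[component]]$shape,
                            derivative = model[[component]]$derivative)
      }
    }
  }
  nuis <- if (!is.null(drift_cutoff)) {
    cosine_drift_basis(grid, drift_cutoff)
  } else NULL
  build_design_batch(specs, grid, nuisance = nuis, intercept = intercept)
}

#' The standard MID contrast library
#'
#' The seven contrasts studied in the simulation and real-data comparisons,
#' defined on the canonical (non-derivative) columns shared by the
#' cue-feedback and saturated models.
#'
#' @param column_names Design column names to align the weights to (e.g.
#'   `task_column_names(design)` or `design$column_names`).
#' @return Named list of [contrast_spec()]s: `Cue:LW-Neut`, `Cue:LL-Neut`,
#'   `Cue:LW-Base`, `FB:WHit-WMiss`, `FB:LHit-LMiss`, `FB:LWHit-NeutHit`,
#'   `FB:LWHit-Base`.
#' @export
contrast_library <- function(column_names) {
  defs <- list(
    "Cue:LW-Neut" = c(Cue_LargeWin = 1, Cue_Neutral = -1),
    "Cue:LL-Neut" = c(Cue_LargeLoss = 1, Cue_Neutral = -1),
    "Cue:LW-Base" = c(Cue_LargeWin = 1),
    "FB:WHit-WMiss" = c(FB_LargeWin_Hit = 0.5, FB_SmallWin_Hit = 0.5,
                        FB_LargeWin_Miss = -0.5, FB_SmallWin_Miss = -0.5),
    "FB:LHit-LMiss" = c(FB_LargeLoss_Hit = 0.5, FB_SmallLoss_Hit = 0.5,
                        FB_LargeLoss_Miss = -0.5, FB_SmallLoss_Miss = -0.5),
    "FB:LWHit-NeutHit" = c(FB_LargeWin_Hit = 1, FB_Neutral_Hit = -1),
    "FB:LWHit-Base" = c(FB_LargeWin_Hit = 1)
  )
  out <- lapply(names(defs), function(nm) {
    missing <- setdiff(names(defs[[nm]]), column_names)
    if (length(missing) > 0) {
      stop(sprintf("contrast '%s' is undefined for this model (no column %s)",
                   nm, paste(missing, collapse = ", ")), call. = FALSE)
    }
    contrast_spec(defs[[nm]], column_names, name = nm)
  })
  stats::setNames(out, names(defs))
}

#' Export a schedule as BIDS-style event rows
#'
#' One data.frame per run with columns `onset`, `duration`, `trial_type`
#' (component and condition, e.g. `cue_LargeWin`, `feedback_LargeWin_hit`),
#' `response_time` and `outcome`, suitable for [write_events_tsv()].
#'
#' @param schedule A [generate_mid_schedule()] result.
#' @return A list of `event_table`s, one per run.
#' @export
schedule_to_bids <- function(schedule) {
  comps <- c("cue", "fixation", "probe", "feedback")
  rows <- do.call(rbind, lapply(comps, function(component) {
    tm <- component_timing(schedule, component)
    suffix <- if (component == "feedback") {
      paste(schedule$cue_type, tolower(ifelse(schedule$outcome == "Hit",
                                              "hit", "miss")), sep = "_")
    } else schedule$cue_type
    data.frame(onset = tm$onset, duration = tm$duration,
               trial_type = paste(component, suffix, sep = "_"),
               response_time = schedule$response_time,
               outcome = schedule$outcome, run = schedule$run,
               stringsAsFactors = FALSE)
  }))
  lapply(sort(unique(rows$run)), function(r) {
    df <- rows[rows$run == r, , drop = FALSE]
    event_table(onset = df$onset, duration = df$duration, run = r,
                trial_type = df$trial_type,
                response_time = df$response_time, outcome = df$outcome)
  })
}
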