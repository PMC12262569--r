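#' Run a midvif analysis from a configuration
#'
#' Dispatches the four entry points (`diagnose`, `mid-generate`, `simulate`,
#' `grouptest`) from a structured configuration: a named list or a path to a
#' YAML file.  Every run writes its outputs plus a provenance file
#' (`<command>_config.yaml` copy of the resolved config including the seed
#' and package version) into `out_dir`, which is created when missing.
#' Unknown configuration keys are rejected with a field-level message so
#' typos never silently change an analysis.
#'
#' Recognised keys per command:
#' \describe{
#'   \item{diagnose}{`design_tsv` (from [write_design_tsv()]) or
#'     `events_tsv` + `model`; optional `contrasts` (named expressions;
#'     default: the standard MID contrast library).}
#'   \item{mid-generate}{`subjects`, optional `runs`, `trials_per_run`;
#'     writes one BIDS events TSV per subject and run.}
#'   \item{simulate}{optional `scenarios`, `models`, `subjects`, `datasets`,
#'     `alpha`, `oversampling`, `figures`.}
#'   \item{grouptest}{`maps_dir` (NIfTI files, needs RNifti) or `maps_rds`;
#'     `sites_tsv` (columns subject, site); optional `t_thresh`, `alpha`,
#'     `max_perms`.}
#' }
#'
#' @param config Named list or path to a YAML file.  Must contain `command`,
#'   `out_dir` and `seed`.
#' @return Invisibly, a list with `files` written and the computed `result`.
#' @export
run_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  common <- c("command", "out_dir", "seed")
  for (k in common) {
    if (is.null(config[[k]])) {
      stop(sprintf("config field '%s' is required", k), call. = FALSE)
    }
  }
  allowed <- list(
    "diagnose" = c("design_tsv", "events_tsv", "model", "contrasts",
                   "oversampling"),
    "mid-generate" = c("subjects", "runs", "trials_per_run"),
    "simulate" = c("scenarios", "models", "subjects", "datasets", "alpha",
                   "oversampling", "figures"),
    "grouptest" = c("maps_dir", "maps_rds", "sites_tsv", "t_thresh", "alpha",
                    "max_perms")
  )
  cmd <- config$command
  if (!cmd %in% names(allowed)) {
    stop(sprintf("unknown command '%s'; available: %s", cmd,
                 paste(names(allowed), collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(config), c(common, allowed[[cmd]]))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s) for %s: %s", cmd,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  set.seed(seed)
  result <- switch(cmd,
                   "diagnose" = cmd_diagnose(config, out_dir, seed),
                   "mid-generate" = cmd_mid_generate(config, out_dir, seed),
                   "simulate" = cmd_simulate(config, out_dir, seed),
                   "grouptest" = cmd_grouptest(config, out_dir, seed))
  prov <- config
  prov$package_version <- as.character(utils::packageVersion("midvif"))
  prov_path <- file.path(out_dir, paste0(sub("-", "_", cmd), "_config.yaml"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(prov, prov_path)
  } else {
    dput(prov, prov_path)
  }
  invisible(list(files = c(result$files, prov_path),
                 result = result$result))
}

cmd_diagnose <- function(config, out_dir, seed) {
  if (!is.null(config$design_tsv)) {
    design <- read_design_tsv(config$design_tsv)
  } else if (!is.null(config$events_tsv)) {
    os <- if (is.null(config$oversampling)) 50 else config$oversampling
    design <- design_from_events_files(config$events_tsv, oversampling = os)
  } else {
    stop("diagnose needs `design_tsv` or `events_tsv`", call. = FALSE)
  }
  contrasts <- if (is.null(config$contrasts)) {
    tryCatch(contrast_library(design$column_names),
             error = function(e) {
               # not an MID design: fall back to elementary task contrasts
               nm <- task_column_names(design)
               stats::setNames(lapply(nm, function(j) {
                 contrast_spec(stats::setNames(1, j), design$column_names,
                               name = j)
               }), nm)
             })
  } else {
    stats::setNames(
      lapply(names(config$contrasts), function(nm) {
        parse_contrast(config$contrasts[[nm]], design$column_names,
                       name = nm)
      }), names(config$contrasts))
  }
  rep <- vif_report(design, contrasts)
  files <- render_report(rep, out_dir, "diagnose", seed, figures = FALSE)
  list(files = files, result = rep)
}

cmd_mid_generate <- function(config, out_dir, seed) {
  n_sub <- config$subjects
  if (is.null(n_sub)) stop("mid-generate needs `subjects`", call. = FALSE)
  n_runs <- if (is.null(config$runs)) 2L else as.integer(config$runs)
  tpr <- if (is.null(config$trials_per_run)) 50L
         else as.integer(config$trials_per_run)
  files <- character(0)
  for (s in seq_len(n_sub)) {
    sched <- generate_mid_schedule(seed = seed + s, n_runs = n_runs,
                                   trials_per_run = tpr)
    bids <- schedule_to_bids(sched)
    for (r in seq_along(bids)) {
      path <- file.path(out_dir,
                        sprintf("sub-%03d_run-%02d_events.tsv", s, r))
      write_events_tsv(bids[[r]], path)
      files <- c(files, path)
    }
  }
  list(files = files, result = NULL)
}

cmd_simulate <- function(config, out_dir, seed) {
  scen_names <- if (is.null(config$scenarios)) {
    names(sim_scenarios())
  } else config$scenarios
  models <- if (is.null(config$models)) {
    c("cuefeedback", "saturated")
  } else config$models
  cfg <- sim_config(
    n_subjects = if (is.null(config$subjects)) 500L else config$subjects,
    n_datasets = if (is.null(config$datasets)) 1000L else config$datasets,
    alpha = if (is.null(config$alpha)) 0.05 else config$alpha,
    seed = seed)
  os <- if (is.null(config$oversampling)) 50 else config$oversampling
  res <- run_scenarios(sim_scenarios(scen_names), models = models,
                       config = cfg, oversampling = os)
  files <- render_report(res, out_dir, "simulate", seed,
                         figures = isTRUE(config$figures))
  list(files = files, result = res)
}

cmd_grouptest <- function(config, out_dir, seed) {
  if (is.null(config$sites_tsv)) stop("grouptest needs `sites_tsv`",
                                      call. = FALSE)
  sites_df <- utils::read.delim(config$sites_tsv, sep = "\t",
                                stringsAsFactors = FALSE)
  if (!all(c("subject", "site") %in% names(sites_df))) {
    stop("sites_tsv needs columns `subject` and `site`", call. = FALSE)
  }
  if (!is.null(config$maps_dir)) {
    maps <- read_nifti_maps(config$maps_dir, sites_df$subject)
  } else {
    stop("grouptest needs `maps_dir`", call. = FALSE)
  }
  res <- cluster_permutation_test(
    maps, sites_df$site,
    t_thresh = if (is.null(config$t_thresh)) 3.1 else config$t_thresh,
    alpha = if (is.null(config$alpha)) 0.05 else config$alpha,
    max_perms = if (is.null(config$max_perms)) 10000 else config$max_perms)
  path <- file.path(out_dir, "grouptest_clusters.tsv")
  write_tsv_with_seed(res$clusters, path, seed)
  files <- path
  if (requireNamespace("RNifti", quietly = TRUE)) {
    tpath <- file.path(out_dir, "grouptest_tmap.nii.gz")
    dpath <- file.path(out_dir, "grouptest_dmap.nii.gz")
    RNifti::writeNifti(res$t_map, tpath)
    RNifti::writeNifti(res$d_map, dpath)
    files <- c(files, tpath, dpath)
  }
  list(files = files, result = res)
}

#' Build a generic first-level design from BIDS events files
#'
#' One boxcar regressor per `trial_type`, convolved with the canonical HRF;
#' one file per run; the grid covers each run up to its last event offset,
#' rounded up to whole scans.
#'
#' @param paths Character vector of per-run events TSV paths.
#' @param dt Scan interval in seconds (default 0.8).
#' @param oversampling Microtime factor.
#' @return A `design_matrix` with an intercept.
#' @export
design_from_events_files <- function(paths, dt = 0.8, oversampling = 50) {
  runs <- lapply(seq_along(paths), function(r) {
    read_events_tsv(paths[r], run = r)
  })
  ev <- do.call(rbind, lapply(runs, as.data.frame))
  n_scans <- vapply(runs, function(e) {
    as.integer(ceiling(max(e$onset + e$duration) / dt))
  }, integer(1))
  grid <- time_grid(n_scans, dt = dt, oversampling = oversampling)
  types <- unique(ev$trial_type)
  specs <- lapply(types, function(tt) {
    i <- ev$trial_type == tt
    list(events = event_table(onset = ev$onset[i], duration = ev$duration[i],
                              run = ev$run[i]),
         shape = "boxcar", derivative = FALSE)
  })
  names(specs) <- types
  build_design_batch(specs, grid)
}

# read one NIfTI map per subject id from a directory (files must contain the
# subject id in their name)
read_nifti_maps <- function(dir, subjects) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI maps requires the RNifti package", call. = FALSE)
  }
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  lapply(subjects, function(s) {
    hit <- files[grepl(s, basename(files), fixed = TRUE)]
    if (length(hit) != 1L) {
      stop(sprintf("expected exactly one map for subject '%s', found %d",
                   s, length(hit)), call. = FALSE)
    }
    as.array(RNifti::readNifti(hit))
  })
}
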