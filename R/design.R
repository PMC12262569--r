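#' Assemble a design matrix
#'
#' Binds named task regressor sets (matrices sampled on a shared grid, runs
#' concatenated along time), optional nuisance regressors, and an intercept
#' into a design matrix object that records which columns are task columns.
#'
#' @param task Named list of numeric matrices (or vectors), one per regressor
#'   set, all with `sum(grid$n_scans_per_run)` rows. Multi-column sets (e.g. a
#'   regressor plus its temporal derivative) get their column names suffixed.
#' @param grid The [time_grid()] the regressors were sampled on.
#' @param nuisance Optional matrix of nuisance regressors (drift, motion).
#' @param intercept Add a single intercept column spanning the concatenated
#'   runs? Default `TRUE`.
#' @return An object of class `design_matrix` with fields `values`,
#'   `column_names`, `grid`, `task_cols` (integer indices).
#' @export
assemble_design <- function(task, grid, nuisance = NULL, intercept = TRUE) {
  stopifnot(inherits(grid, "time_grid"))
  if (length(task) == 0 || is.null(names(task)) || any(names(task) == "")) {
    stop("`task` must be a non-empty named list", call. = FALSE)
  }
  ntot <- total_scans(grid)
  cols <- list()
  for (nm in names(task)) {
    m <- task[[nm]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    if (nrow(m) != ntot) {
      stop(sprintf("regressor '%s' has %d rows; the grid has %d scans",
                   nm, nrow(m), ntot), call. = FALSE)
    }
    cn <- if (ncol(m) == 1L) nm else {
      suf <- colnames(m)
      if (is.null(suf)) suf <- as.character(seq_len(ncol(m)))
      ifelse(suf %in% c("x", "1"), nm, paste0(nm, "_", sub("^x_", "", suf)))
    }
    colnames(m) <- cn
    cols[[length(cols) + 1L]] <- m
  }
  X <- do.call(cbind, cols)
  task_cols <- seq_len(ncol(X))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (ncol(nuisance) > 0) {
      if (nrow(nuisance) != ntot) stop("nuisance length mismatch", call. = FALSE)
      if (is.null(colnames(nuisance))) {
        colnames(nuisance) <- sprintf("nuisance_%d", seq_len(ncol(nuisance)))
      }
      X <- cbind(X, nuisance)
    }
  }
  if (intercept) X <- cbind(X, intercept = 1)
  if (anyDuplicated(colnames(X))) {
    stop(sprintf("duplicate column names: %s",
                 paste(unique(colnames(X)[duplicated(colnames(X))]),
                       collapse = ", ")), call. = FALSE)
  }
  new_design_matrix(X, grid, task_cols)
}

new_design_matrix <- function(X, grid, task_cols) {
  structure(list(values = X, column_names = colnames(X), grid = grid,
                 task_cols = as.integer(task_cols)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d columns (%d task)\n",
              nrow(x$values), ncol(x$values), length(x$task_cols)))
  cat("  task: ", paste(utils::head(x$column_names[x$task_cols], 8),
                        collapse = ", "),
      if (length(x$task_cols) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname assemble_design
#' @param design A `design_matrix`.
#' @export
task_column_names <- function(design) {
  design$column_names[design$task_cols]
}

#' Write / read a design matrix as TSV
#'
#' Plain TSV with a header row of column names; a comment line records which
#' columns are task columns and the grid so the file round-trips.
#'
#' @param design A `design_matrix`.
#' @param path Output path.
#' @export
write_design_tsv <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# task_cols=%s",
                     paste(design$task_cols, collapse = ",")), con)
  writeLines(sprintf("# dt=%g runs=%s oversampling=%d", design$grid$dt,
                     paste(design$grid$n_scans_per_run, collapse = ","),
                     design$grid$oversampling), con)
  utils::write.table(design$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  header <- readLines(path, n = 2L)
  task_cols <- as.integer(strsplit(sub("# task_cols=", "", header[1]),
                                   ",")[[1]])
  m <- regmatches(header[2],
                  regexec("# dt=([0-9.e+-]+) runs=([0-9,]+) oversampling=([0-9]+)",
                          header[2]))[[1]]
  X <- as.matrix(utils::read.delim(path, sep = "\t", comment.char = "#",
                                   check.names = FALSE))
  grid <- time_grid(as.integer(strsplit(m[3], ",")[[1]]),
                    dt = as.numeric(m[2]), oversampling = as.integer(m[4]))
  new_design_matrix(X, grid, task_cols)
}

# Batched design construction: builds every regressor of every run in one
# pass, sharing the FFTs of the canonical and derivative kernels. `specs` is a
# named list with elements list(events=, shape=, derivative=).
build_design_batch <- function(specs, grid, kernel = NULL, nuisance = NULL,
                               intercept = TRUE) {
  dtm <- dt_micro(grid)
  if (is.null(kernel)) kernel <- canonical_hrf(dtm)
  dkernel <- temporal_derivative_kernel(kernel)
  os <- grid$oversampling
  p <- length(specs)
  runs <- vector("list", n_runs(grid))
  for (r in seq_len(n_runs(grid))) {
    nr <- grid$n_scans_per_run[r]
    n_micro <- nr * os
    Nmat <- matrix(0, n_micro, p)
    for (j in seq_len(p)) {
      sp <- specs[[j]]
      ev <- sp$events[sp$events$run == r, , drop = FALSE]
      Nmat[, j] <- neural_signal(ev, n_micro, dtm, sp$shape)
    }
    conv <- convolve_cols(Nmat, kernel$values)
    idx <- (seq_len(nr) - 1L) * os + 1L
    canon <- conv[idx, , drop = FALSE]
    dflags <- vapply(specs, function(s) isTRUE(s$derivative), logical(1))
    if (any(dflags)) {
      dconv <- convolve_cols(Nmat[, dflags, drop = FALSE], dkernel$values)
      deriv <- dconv[idx, , drop = FALSE]
    } else {
      deriv <- NULL
    }
    runs[[r]] <- list(canon = canon, deriv = deriv)
  }
  canon <- do.call(rbind, lapply(runs, `[[`, "canon"))
  colnames(canon) <- names(specs)
  dflags <- vapply(specs, function(s) isTRUE(s$derivative), logical(1))
  cols <- list()
  di <- 0L
  if (any(dflags)) {
    deriv <- do.call(rbind, lapply(runs, `[[`, "deriv"))
  }
  for (j in seq_len(p)) {
    cols[[length(cols) + 1L]] <- canon[, j, drop = FALSE]
    if (dflags[j]) {
      di <- di + 1L
      d <- deriv[, di, drop = FALSE]
      colnames(d) <- paste0(names(specs)[j], "_derivative")
      cols[[length(cols) + 1L]] <- d
    }
  }
  X <- do.call(cbind, cols)
  task_cols <- seq_len(ncol(X))
  if (!is.null(nuisance) && ncol(as.matrix(nuisance)) > 0) {
    X <- cbind(X, as.matrix(nuisance))
  }
  if (intercept) X <- cbind(X, intercept = 1)
  new_design_matrix(X, grid, task_cols)
}
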