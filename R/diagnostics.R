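check_full_rank <- function(X, what = "design") {
  XtX <- crossprod(X)
  k <- tryCatch(kappa(XtX, exact = FALSE), error = function(e) Inf)
  if (!is.finite(k) || k > 1e10) {
    # report the offending column set via QR pivoting
    qrX <- qr(X)
    extra <- if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
      sprintf("; dependent column(s): %s", paste(bad, collapse = ", "))
    } else ""
    stop(sprintf("%s is (near-)singular (condition number %.3g)%s",
                 what, k, extra), call. = FALSE)
  }
  XtX
}

#' Contrast estimation efficiency
#'
#' `efficiency = 1 / (c (X'X)^-1 c')`, the inverse of the design-driven part
#' of the contrast variance: `Var(c b-hat) = sigma^2 / efficiency`.  Doubling
#' the efficiency halves the contrast variance.  Efficiency only ranks
#' designs; it has no absolute benchmark, which is what the VIFs add.
#'
#' @param design A `design_matrix` (full column rank).
#' @param contrast A [contrast_spec()], a named weight vector, or a numeric
#'   vector aligned to the design columns.
#' @return Positive scalar.
#' @export
efficiency <- function(design, contrast) {
  X <- design$values
  cc <- align_contrast(design, contrast)
  XtX <- check_full_rank(X)
  v <- drop(crossprod(cc, solve(XtX, cc)))
  1 / v
}

#' Traditional variance inflation factor
#'
#' The ratio of `Var(b-hat_j)` in the full model to its variance in the
#' reduced model containing only the intercept and regressor j.  Equals 1 when
#' the regressor is orthogonal to every other (centred) column, and grows as
#' `1 / (1 - R^2_j)` with the regressor's multiple correlation on the rest.
#'
#' @param design A `design_matrix` containing an intercept column.
#' @param column Column name (a non-intercept column).
#' @return Scalar `>= 1` up to floating point.
#' @export
tvif <- function(design, column) {
  X <- design$values
  cn <- design$column_names
  if (!column %in% cn) {
    stop(sprintf("no column '%s' in design", column), call. = FALSE)
  }
  ic <- intercept_col(design)
  if (column == cn[ic]) stop("tVIF is undefined for the intercept",
                             call. = FALSE)
  XtX <- check_full_rank(X)
  j <- match(column, cn)
  var_full <- solve(XtX)[j, j]
  Xr <- X[, c(ic, j)]
  var_red <- solve(crossprod(Xr))[2L, 2L]
  var_full / var_red
}

intercept_col <- function(design) {
  X <- design$values
  ic <- which(apply(X, 2L, function(col) all(col == col[1L]) && col[1L] != 0))
  if (length(ic) == 0) {
    stop("design has no intercept column; VIFs require one", call. = FALSE)
  }
  ic[1L]
}

#' Contrast-based variance inflation factor
#'
#' Variance inflation of a contrast estimate relative to a best-case reduced
#' model, extending the tVIF from single coefficients to contrasts.  The
#' contrast's effective regressor `x_c = X_task c' (c c')^-1` is the signal
#' whose coefficient equals `c b`; the cVIF is the variance of `c b-hat` under
#' the full design divided by the variance of the `x_c` coefficient in the
#' reduced model containing only an intercept and `x_c`.  For an elementary
#' contrast (single +1 weight) this reduces exactly to [tvif()] of that
#' column.  Unlike tVIF it detects condition-signal overlap that survives
#' reparameterisation: under any scaled-orthogonal recoding of the task
#' columns (e.g. sum/difference coding, which drives all tVIFs to 1) the cVIF
#' of the correspondingly mapped contrast is unchanged.  Task columns are
#' expected to be condition regressors (condition vs baseline); nuisance
#' columns enter the full-model variance but never the reduced model.
#'
#' @inheritParams efficiency
#' @return Scalar `>= 1` up to floating point.
#' @export
cvif <- function(design, contrast) {
  X <- design$values
  cc <- align_contrast(design, contrast)
  if (all(cc == 0)) stop("contrast has no nonzero weight", call. = FALSE)
  if (any(cc[-design$task_cols] != 0)) {
    stop("cVIF contrasts may only weight task columns", call. = FALSE)
  }
  ic <- intercept_col(design)
  ct <- cc[design$task_cols]
  Xt <- X[, design$task_cols, drop = FALSE]
  XtX <- check_full_rank(X)
  var_full <- drop(crossprod(cc, solve(XtX, cc)))
  x_c <- drop(Xt %*% ct) / sum(ct^2)
  Xr <- cbind(X[, ic], x_c)
  XrtXr <- crossprod(Xr)
  if (kappa(XrtXr) > 1e10) {
    stop("contrast is not estimable: effective regressor is degenerate",
         call. = FALSE)
  }
  var_red <- solve(XrtXr)[2L, 2L]
  var_full / var_red
}

#' Collinearity report for a design and a set of contrasts
#'
#' Applies [efficiency()], [cvif()] to every contrast and [tvif()] to every
#' non-intercept column, flagging contrasts whose cVIF exceeds the working
#' thresholds of 5 (inspect the data for outliers) and 20 (excessive; the
#' contrast is effectively not estimable with useful precision).
#'
#' @param design A `design_matrix`.
#' @param contrasts A named list of contrasts (see [efficiency()]).
#' @param omitted Optional character vector naming regressors that were
#'   deliberately dropped from the model.  Omission changes the model, not the
#'   parameterisation, so its bias cannot be assessed by any VIF; the report
#'   warns and records the names instead of silently ignoring them.
#' @return A data.frame of class `vif_report` (one row per contrast:
#'   `contrast`, `efficiency`, `cvif`, `flag`) with per-column tVIFs in
#'   `attr(, "tvif")` and the flag thresholds in `attr(, "thresholds")`.
#' @export
vif_report <- function(design, contrasts, omitted = NULL) {
  if (is.null(names(contrasts))) {
    names(contrasts) <- vapply(contrasts, function(cs) {
      nm <- attr(cs, "name")
      if (is.null(nm)) "contrast" else nm
    }, character(1))
  }
  eff <- vapply(contrasts, function(cs) efficiency(design, cs), numeric(1))
  cv <- vapply(contrasts, function(cs) cvif(design, cs), numeric(1))
  flag <- ifelse(cv > 20, ">20", ifelse(cv > 5, ">5", "ok"))
  out <- data.frame(contrast = names(contrasts), efficiency = eff,
                    cvif = cv, flag = flag, row.names = NULL,
                    stringsAsFactors = FALSE)
  ic <- intercept_col(design)
  cols <- setdiff(design$column_names, design$column_names[ic])
  attr(out, "tvif") <- vapply(cols, function(j) tvif(design, j), numeric(1))
  attr(out, "thresholds") <- c(inspect = 5, excessive = 20)
  if (!is.null(omitted) && length(omitted) > 0) {
    attr(out, "omitted") <- omitted
    warning(sprintf(paste("regressor(s) %s were omitted from the model:",
                          "omission changes the model itself and can bias the",
                          "remaining estimates; VIFs cannot quantify this"),
                    paste(omitted, collapse = ", ")), call. = FALSE)
  }
  class(out) <- c("vif_report", "data.frame")
  out
}

#' @export
print.vif_report <- function(x, ...) {
  cat("Contrast collinearity report (cVIF flags: >5 inspect, >20 excessive)\n")
  print.data.frame(x, digits = 4)
  tv <- attr(x, "tvif")
  cat("\nPer-column tVIF:\n")
  print(round(tv, 3))
  if (!is.null(attr(x, "omitted"))) {
    cat("\nOmitted regressors (bias risk, not assessable by VIF):",
        paste(attr(x, "omitted"), collapse = ", "), "\n")
  }
  invisible(x)
}
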