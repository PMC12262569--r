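write_tsv_with_seed <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", if (is.null(seed)) "NA" else seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render module results as report files
#'
#' Writes a tidy TSV (always, with a `# seed=` provenance line) and, when
#' ggplot2 is available and `figures = TRUE`, companion figures: a bias
#' heat-map grid for simulation summaries (one cell per scenario x model x
#' contrast, boxed when the type I error rate is inflated) and a cVIF bar
#' chart for collinearity reports with the 5/20 thresholds marked.  A missing
#' figure backend degrades to TSV-only with a warning.
#'
#' @param results A `sim_summary`, `vif_report`, or plain data.frame.
#' @param dir Output directory (created if missing).
#' @param name Basename for the report files.
#' @param seed Seed to record in the provenance line.
#' @param figures Attempt figures? Default `TRUE` for result types that have
#'   one.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(results, dir = ".", name = "report", seed = NULL,
                          figures = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  tsv <- file.path(dir, paste0(name, ".tsv"))
  df <- as.data.frame(results)
  if (inherits(results, "vif_report")) {
    tv <- attr(results, "tvif")
    write_tsv_with_seed(df, tsv, seed)
    tvif_path <- file.path(dir, paste0(name, "_tvif.tsv"))
    write_tsv_with_seed(data.frame(column = names(tv), tvif = unname(tv)),
                        tvif_path, seed)
    files <- c(tsv, tvif_path)
  } else {
    write_tsv_with_seed(df, tsv, seed)
    files <- tsv
  }
  if (figures && (inherits(results, "sim_summary") ||
                  inherits(results, "vif_report"))) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      warning("ggplot2 not available; wrote TSV only", call. = FALSE)
    } else {
      fig <- file.path(dir, paste0(name, ".png"))
      p <- if (inherits(results, "sim_summary")) {
        plot_bias_grid(results)
      } else {
        plot_cvif_bars(results)
      }
      grDevices::png(fig, width = 1400, height = 900, res = 150)
      print(p)
      grDevices::dev.off()
      files <- c(files, fig)
    }
  }
  invisible(files)
}

#' Heat-map of simulation bias across scenarios, models and contrasts
#'
#' One cell per (scenario, model, contrast) coloured by the average group
#' t-statistic of the bias; cells with inflated type I error are outlined,
#' cells with true signal are greyed (their rejection rate is power, not an
#' error rate).
#'
#' @param summary A `sim_summary` from [run_scenarios()].
#' @return A ggplot object.
#' @export
plot_bias_grid <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for figures", call. = FALSE)
  }
  df <- as.data.frame(summary)
  df$bias_plot <- ifelse(df$signal, NA_real_, df$bias_t)
  df$outline <- !is.na(df$inflated) & df$inflated
  aes <- ggplot2::aes
  ggplot2::ggplot(df, aes(x = .data[["contrast"]], y = .data[["scenario"]])) +
    ggplot2::geom_tile(aes(fill = .data[["bias_plot"]]), colour = "grey40") +
    ggplot2::geom_tile(data = df[df$outline, , drop = FALSE],
                       fill = NA, colour = "black", linewidth = 1.2) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey70",
                                  name = "avg bias t") +
    ggplot2::facet_wrap(~model, ncol = 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of contrast cVIFs with working thresholds
#'
#' @param report A `vif_report`.
#' @return A ggplot object.
#' @export
plot_cvif_bars <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for figures", call. = FALSE)
  }
  df <- as.data.frame(report)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["contrast"]],
                                   y = .data[["cvif"]],
                                   fill = .data[["flag"]])) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(5, 20), linetype = "dashed") +
    ggplot2::annotate("text", x = Inf, y = c(5, 20),
                      label = c("inspect (5)", "excessive (20)"),
                      hjust = 1.1, vjust = -0.4, size = 3) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
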