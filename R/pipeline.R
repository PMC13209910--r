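# End-to-end runner: ingest -> flag -> screen -> (per drug) onset ->
# Weibull fit, with all artifacts written under one output directory and
# a deterministic JSON run report.

#' Assemble a pipeline run configuration
#'
#' @param drug,reaction,demographic paths to the three CSV tables.
#' @param case_def a [case_definition()] or a path readable by
#'   [read_case_definition()]; `NULL` uses the packaged GBS default.
#' @param min_reports,alpha signal-rule thresholds.
#' @param unit counting unit for screening (`"report"` or `"pair"`).
#' @param date_window validity window for cleaned dates.
#' @param tto_range closed onset analysis window in days.
#' @param fit_min_n minimum onset sample size for a Weibull fit.
#' @param ci Weibull CI method (`"wald"` or `"bootstrap"`).
#' @param tto_drugs drugs to carry into onset analysis: `"signals"`
#'   (default; every signal drug) or an explicit character vector.
#' @param seed seed for any randomness (bootstrap CIs).
#' @param out_dir output directory; `NULL` disables file output.
#' @param col_map optional schema mapping for [read_tables()].
#' @return A `run_config` list.
#' @export
run_config <- function(drug, reaction, demographic, case_def = NULL,
                       min_reports = 100, alpha = 0.05,
                       unit = c("report", "pair"),
                       date_window = as.Date(c("1960-01-01", "2025-02-28")),
                       tto_range = c(0.5, 365.5), fit_min_n = 10,
                       ci = c("wald", "bootstrap"), tto_drugs = "signals",
                       seed = 1, out_dir = NULL, col_map = NULL) {
  unit <- match.arg(unit)
  ci <- match.arg(ci)
  stopifnot(min_reports > 0, alpha > 0, alpha < 1,
            tto_range[1] < tto_range[2], fit_min_n > 0)
  if (is.null(case_def)) case_def <- case_definition()
  if (is.character(case_def)) case_def <- read_case_definition(case_def)
  structure(list(drug = drug, reaction = reaction, demographic = demographic,
                 case_def = case_def, min_reports = min_reports,
                 alpha = alpha, unit = unit, date_window = as.Date(date_window),
                 tto_range = tto_range, fit_min_n = fit_min_n, ci = ci,
                 tto_drugs = tto_drugs, seed = as.integer(seed),
                 out_dir = out_dir, col_map = col_map),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full screening and onset pipeline
#'
#' Executes ingest (read, deduplicate, suspected filter, merge), case
#' flagging, disproportionality screening, and -- for the selected
#' drugs -- time-to-onset construction and Weibull fitting. When
#' `config$out_dir` is set, writes `signals.csv`, `volcano.csv` (+
#' metadata JSON), one `onset_<drug>.csv` per analyzed drug,
#' `weibull_fits.csv` and `run_report.json`. The run report contains
#' only deterministic content (stage counts, the flagged proportion,
#' verdicts, seed and package version), so identical inputs give
#' byte-identical reports.
#'
#' @param config a [run_config()].
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tables <- stage("read_tables",
                  read_tables(config$drug, config$reaction,
                              config$demographic, col_map = config$col_map))
  counts_read <- vapply(tables, nrow, integer(1))
  tables <- stage("deduplicate", deduplicate_tables(tables))
  counts_dedup <- vapply(tables, nrow, integer(1))
  suspected <- stage("filter_suspected", filter_suspected(tables))
  records <- stage("merge_tables", merge_tables(suspected))
  records <- stage("flag_events", flag_events(records, config$case_def))
  screen <- stage("screen_signals",
                  screen_signals(records, min_reports = config$min_reports,
                                 alpha = config$alpha, unit = config$unit))

  n_flagged <- sum(records$gbs_case)
  prop_pct <- report_proportion(n_flagged, nrow(records))
  signal_drugs <- screen$drug[screen$is_signal]

  tto_drugs <- config$tto_drugs
  if (identical(tto_drugs, "signals")) tto_drugs <- signal_drugs
  onset_tables <- list()
  fits <- list()
  for (dg in tto_drugs) {
    ot <- stage(paste0("onset:", dg),
                build_onset_table(tables, dg, case_def = config$case_def,
                                  date_window = config$date_window,
                                  tto_range = config$tto_range))
    onset_tables[[dg]] <- ot
    fits[[dg]] <- if (nrow(ot) >= config$fit_min_n) {
      tryCatch(fit_weibull(ot$t_days, fit_min_n = config$fit_min_n,
                           ci = config$ci, seed = config$seed),
               error = function(e) NULL)
    } else NULL
  }

  fit_rows <- lapply(names(fits), function(dg) {
    f <- fits[[dg]]
    ot <- onset_tables[[dg]]
    data.frame(
      drug = dg, n_onset = nrow(ot),
      median_t = if (nrow(ot)) median(ot$t_days) else NA_real_,
      min_t = if (nrow(ot)) min(ot$t_days) else NA_real_,
      max_t = if (nrow(ot)) max(ot$t_days) else NA_real_,
      alpha = if (is.null(f)) NA_real_ else f$alpha,
      alpha_lo = if (is.null(f)) NA_real_ else f$alpha_ci95[1],
      alpha_hi = if (is.null(f)) NA_real_ else f$alpha_ci95[2],
      beta = if (is.null(f)) NA_real_ else f$beta,
      beta_lo = if (is.null(f)) NA_real_ else f$beta_ci95[1],
      beta_hi = if (is.null(f)) NA_real_ else f$beta_ci95[2],
      failure_pattern = if (is.null(f)) NA_character_ else f$failure_pattern,
      stringsAsFactors = FALSE)
  })
  fit_table <- if (length(fit_rows)) do.call(rbind, fit_rows) else NULL

  report <- list(
    package = "jaderpv",
    version = as.character(packageVersion("jaderpv")),
    seed = config$seed,
    thresholds = list(min_reports = config$min_reports,
                      alpha = config$alpha, unit = config$unit,
                      fit_min_n = config$fit_min_n, ci = config$ci),
    counts = list(
      rows_read = as.list(counts_read),
      rows_after_dedup = as.list(counts_dedup),
      suspected_drug_rows = nrow(suspected$drug),
      merged_records = nrow(records),
      flagged_records = n_flagged,
      flagged_proportion_pct = prop_pct,
      drugs_screened = nrow(screen),
      tests_performed = nrow(screen),
      signals = length(signal_drugs)
    ),
    signal_drugs = as.list(signal_drugs),
    weibull_fits = if (is.null(fit_table)) list() else
      lapply(seq_len(nrow(fit_table)), function(i) as.list(fit_table[i, ]))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(screen, file.path(config$out_dir, "signals.csv"),
              row.names = FALSE)
    export_volcano(screen, file.path(config$out_dir, "volcano.csv"),
                   alpha = config$alpha)
    for (dg in names(onset_tables)) {
      safe <- gsub("[^A-Za-z0-9._-]+", "_", dg)
      write.csv(onset_tables[[dg]],
                file.path(config$out_dir, paste0("onset_", safe, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(fit_table)) {
      write.csv(fit_table, file.path(config$out_dir, "weibull_fits.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(report,
                         file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(report)
}

#' Export volcano coordinates (and optionally a figure)
#'
#' Always writes the coordinates CSV; a metadata JSON alongside records
#' the significance reference line at y = -log10(alpha). A figure is
#' drawn only when `plot_file` is given and ggplot2 is available.
#'
#' @param results a [screen_signals()] result.
#' @param path CSV output path.
#' @param alpha significance level for the reference line.
#' @param plot_file optional image path (e.g. `.png`).
#' @return The coordinates data frame, invisibly.
#' @export
export_volcano <- function(results, path, alpha = 0.05, plot_file = NULL) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("no screening results to export", call. = FALSE)
  }
  coords <- volcano_coordinates(results, alpha = alpha)
  write.csv(coords, path, row.names = FALSE)
  meta <- list(reference_line = attr(coords, "reference_line"),
               alpha = alpha, x = "ln(ROR)", y = "-log10(p)")
  jsonlite::write_json(meta,
                       paste0(tools::file_path_sans_ext(path), "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(plot_file) && requireNamespace("ggplot2", quietly = TRUE)) {
    gp <- ggplot2::ggplot(coords, ggplot2::aes_string(x = "x", y = "y")) +
      ggplot2::geom_point(ggplot2::aes_string(colour = "class_label"),
                          alpha = 0.7) +
      ggplot2::geom_hline(yintercept = attr(coords, "reference_line"),
                          linetype = "dotted") +
      ggplot2::labs(x = "ln(ROR)", y = expression(-log[10](italic(p))),
                    colour = NULL)
    ggplot2::ggsave(plot_file, gp, width = 7, height = 5)
  }
  invisible(coords)
}
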