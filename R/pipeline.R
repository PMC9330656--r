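#' Run the full calling pipeline on one plate
#'
#' End-to-end orchestration: read (or accept) traces and plate map,
#' baseline-adjust and normalize, compute the noise threshold, call
#' replicates and samples, and assemble a run report. Deterministic given
#' its inputs and config; rerunning produces identical outputs.
#'
#' @param traces A `quic_traces` tibble or a path to a long trace CSV.
#' @param plate_map A `quic_plate_map` tibble or a path to a plate-map CSV.
#' @param config A [calling_config()].
#' @param out_dir Optional directory; when given, `calls.csv` and
#'   `report.json` are written there (created if needed).
#' @param ignore_unmapped Passed to [normalize_traces()].
#' @return A `quic_report` list: `config`, `thresholds` (percent and noise
#'   components plus the effective value), `baselines`, `normalization_max`,
#'   `calls`, `warnings`, `version`.
#' @export
run_calling <- function(traces, plate_map, config = calling_config(),
                        out_dir = NULL, ignore_unmapped = FALSE) {
  if (is.character(traces)) traces <- read_traces(traces)
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  normalized <- normalize_traces(traces, plate_map, config,
                                 ignore_unmapped = ignore_unmapped)
  calls <- call_samples(normalized, config)
  warn <- character(0)
  if (any(calls$underreplicated)) {
    warn <- c(warn, sprintf(
      "%d sample(s) had fewer than %d replicates",
      sum(calls$underreplicated), config$expected_replicates
    ))
  }
  report <- structure(
    list(
      config = unclass(config),
      thresholds = list(
        percent_threshold = config$percent_threshold,
        noise_threshold = attr(calls, "noise_threshold"),
        effective = attr(calls, "threshold")
      ),
      baselines = normalized$baselines,
      normalization_max = normalized$normalization_max,
      calls = calls,
      normalized = normalized,
      warnings = warn,
      version = as.character(utils::packageVersion("rtquic"))
    ),
    class = "quic_report"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_calls(calls, file.path(out_dir, "calls.csv"))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' Stable, timestamp-free serialization so identical runs produce
#' byte-identical reports.
#'
#' @param report A `quic_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  calls <- report$calls
  calls_df <- data.frame(
    sample = calls$sample, subject = calls$subject,
    specimen = as.character(calls$specimen),
    diagnosis = as.character(calls$diagnosis),
    n_replicates = calls$n_replicates,
    n_positive_replicates = calls$n_positive_replicates,
    call = calls$call,
    lag_times = vapply(calls$lag_times, paste, character(1), collapse = ";"),
    endpoint_mean_percent = calls$endpoint_mean_percent
  )
  out <- list(
    schema_version = 1L,
    package_version = report$version,
    config = report$config,
    thresholds = report$thresholds,
    baselines = as.data.frame(report$baselines),
    normalization_max = report$normalization_max,
    calls = calls_df,
    warnings = report$warnings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Diagnostic-accuracy statistics on calls or printed counts
#'
#' Computes every statistic of the diagnostics layer that the supplied
#' structure supports. With a calls table: positivity summaries per
#' (specimen, diagnosis) group, and — when exactly two groups are compared
#' — Fisher's exact test with Cramer's V. With a counts table
#' (`group,positive,total`): the same from printed counts. With paired
#' calls: exact McNemar and Cohen's kappa.
#'
#' @param calls Optional `quic_calls` tibble (or path to a calls CSV).
#' @param counts Optional data frame (or CSV path) with columns
#'   `group,positive,total`.
#' @param paired Optional list of two call tables on the same subjects
#'   (each with `subject` and `call` columns) for agreement statistics.
#' @param compare Optional character vector of two group names (rows of
#'   `counts`, or specimen levels of `calls`) to contrast; defaults to the
#'   first two available.
#' @return A `quic_stats` list: `summaries` (tibble of per-group
#'   positivity), `comparison` (list with `table`, `fisher_p`,
#'   `cramers_v`) when two groups were contrasted, `agreement` (a
#'   `quic_agreement`) when paired calls were given.
#' @export
run_stats <- function(calls = NULL, counts = NULL, paired = NULL,
                      compare = NULL) {
  if (is.null(calls) && is.null(counts) && is.null(paired)) {
    quic_abort("supply calls, counts, or paired call sets",
               "rtquic_validation_error")
  }
  summaries <- NULL
  comparison <- NULL
  agreement <- NULL

  if (!is.null(calls)) {
    if (is.character(calls)) calls <- read_calls(calls)
    grp <- dplyr::summarise(
      dplyr::group_by(calls, .data$specimen, .data$diagnosis),
      positive = sum(.data$call == "positive"),
      total = dplyr::n(), .groups = "drop"
    )
    counts_from_calls <- tibble::tibble(
      group = paste(grp$specimen, grp$diagnosis, sep = "/"),
      positive = grp$positive, total = grp$total
    )
    counts <- if (is.null(counts)) counts_from_calls else counts
  }
  if (!is.null(counts)) {
    if (is.character(counts)) {
      counts <- readr::read_csv(counts, show_col_types = FALSE,
                                progress = FALSE)
    }
    need <- c("group", "positive", "total")
    if (!all(need %in% names(counts))) {
      quic_abort("counts need columns group, positive, total",
                 "rtquic_format_error")
    }
    summaries <- dplyr::bind_rows(lapply(seq_len(nrow(counts)), function(i) {
      s <- sensitivity(counts$positive[i], counts$total[i])
      tibble::tibble(
        group = counts$group[i], n_positive = s$n_positive,
        n_total = s$n_total, estimate = s$estimate,
        ci_low = s$ci_low, ci_high = s$ci_high,
        percent_rounded = s$percent_rounded
      )
    }))
    sel <- compare %||% utils::head(counts$group, 2)
    if (length(sel) == 2 && all(sel %in% counts$group)) {
      i <- match(sel, counts$group)
      tab <- table2x2(
        counts$positive[i[1]], counts$total[i[1]] - counts$positive[i[1]],
        counts$positive[i[2]], counts$total[i[2]] - counts$positive[i[2]]
      )
      attr(tab, "groups") <- sel
      zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
      comparison <- list(
        table = tab,
        fisher_p = fisher_exact(tab),
        cramers_v = if (zero_margin) NA_real_ else cramers_v(tab)
      )
    }
  }
  if (!is.null(paired)) {
    if (!is.list(paired) || length(paired) != 2) {
      quic_abort("paired must be a list of two call tables",
                 "rtquic_validation_error")
    }
    tab <- build_paired_table(paired[[1]], paired[[2]])
    agreement <- cohens_kappa(tab)
    agreement$table <- tab
  }
  structure(
    list(summaries = summaries, comparison = comparison,
         agreement = agreement),
    class = "quic_stats"
  )
}

#' Write a stats result to JSON
#' @param stats A `quic_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  out <- list(schema_version = 1L)
  if (!is.null(stats$summaries)) {
    out$summaries <- as.data.frame(stats$summaries)
  }
  if (!is.null(stats$comparison)) {
    out$comparison <- list(
      groups = attr(stats$comparison$table, "groups"),
      table = as.vector(t(unclass(stats$comparison$table))),
      fisher_p = stats$comparison$fisher_p,
      cramers_v = stats$comparison$cramers_v
    )
  }
  if (!is.null(stats$agreement)) {
    a <- stats$agreement
    out$agreement <- list(
      table = as.vector(t(unclass(a$table))),
      kappa = a$kappa, se_kappa = a$se_kappa,
      ci_low = a$ci_low, ci_high = a$ci_high,
      mcnemar_p = a$mcnemar_p, n_discordant = a$n_discordant, n = a$n
    )
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.quic_report <- function(x, ...) {
  cat("RT-QuIC run report\n")
  cat(sprintf("  threshold: %.3f%% (mode %s; noise component %s)\n",
              x$thresholds$effective, x$config$threshold_mode,
              ifelse(is.na(x$thresholds$noise_threshold), "not used",
                     sprintf("%.3f%%", x$thresholds$noise_threshold))))
  cat(sprintf("  samples: %d (%d positive)\n", nrow(x$calls),
              sum(x$calls$call == "positive")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.quic_stats <- function(x, ...) {
  if (!is.null(x$summaries)) {
    cat("Positivity by group:\n")
    df <- x$summaries
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %s: %d/%d (%d%%), 95%% CI [%.2f, %.2f]\n",
                  df$group[i], df$n_positive[i], df$n_total[i],
                  df$percent_rounded[i], df$ci_low[i], df$ci_high[i]))
    }
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("Fisher exact p = %.4g, Cramer's V = %.3g (%s vs %s)\n",
                x$comparison$fisher_p, x$comparison$cramers_v,
                attr(x$comparison$table, "groups")[1],
                attr(x$comparison$table, "groups")[2]))
  }
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}
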