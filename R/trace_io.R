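#' Read plate-reader fluorescence traces from CSV
#'
#' Reads Thioflavin T fluorescence time series exported from a plate reader.
#' Two dialects are supported: `"long"` (canonical, one row per reading with
#' columns `well,time_h,rfu`) and `"wide"` (one `time_h` column plus one
#' column per well, mimicking common plate-reader exports). Both produce the
#' same in-memory representation; long CSV is the canonical on-disk format
#' and the only one [write_traces()] emits.
#'
#' @param path Path to a CSV file.
#' @param format `"long"` or `"wide"`.
#' @param time_unit Unit of the time column; `"minutes"` is converted to
#'   hours on read. All downstream computation is in hours.
#' @return A `quic_traces` tibble with columns `well`, `time_h`, `rfu`,
#'   sorted by well and time.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("well,time_h,rfu", "A1,0,100", "A1,0.75,110", "A1,1.5,120"), path)
#' read_traces(path)
#' @export
read_traces <- function(path, format = c("long", "wide"),
                        time_unit = c("hours", "minutes")) {
  format <- rlang::arg_match(format)
  time_unit <- rlang::arg_match(time_unit)
  if (!file.exists(path)) {
    quic_abort(sprintf("trace file not found: %s", path), "rtquic_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (format == "long") {
    required <- c("well", "time_h", "rfu")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      quic_abort(
        sprintf("long trace CSV is missing column(s): %s",
                paste(missing, collapse = ", ")),
        "rtquic_format_error"
      )
    }
    long <- dplyr::select(df, dplyr::all_of(required))
  } else {
    if (!"time_h" %in% names(df) || ncol(df) < 2) {
      quic_abort(
        "wide trace CSV needs a 'time_h' column plus one column per well",
        "rtquic_format_error"
      )
    }
    long <- tidyr::pivot_longer(df, -"time_h",
                                names_to = "well", values_to = "rfu")
    long <- dplyr::select(long, "well", "time_h", "rfu")
  }
  if (time_unit == "minutes") long$time_h <- long$time_h / 60
  as_quic_traces(long)
}

#' Validate a data frame of fluorescence traces
#'
#' Checks the invariants every trace set must satisfy: numeric finite rfu,
#' strictly increasing times within each well (duplicated readings are an
#' error, not silently averaged), and at least two readings per well.
#'
#' @param df A data frame with columns `well`, `time_h`, `rfu`.
#' @return A validated `quic_traces` tibble sorted by well and time.
#' @export
as_quic_traces <- function(df) {
  df <- tibble::as_tibble(df)[, c("well", "time_h", "rfu")]
  df$well <- as.character(df$well)
  if (!is.numeric(df$time_h) || !is.numeric(df$rfu)) {
    quic_abort("time_h and rfu must be numeric", "rtquic_validation_error")
  }
  bad <- which(!is.finite(df$rfu))
  if (length(bad) > 0) {
    quic_abort(
      sprintf("non-finite rfu for well %s at row %d",
              df$well[bad[1]], bad[1]),
      "rtquic_validation_error"
    )
  }
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0)) {
    quic_abort("times must be finite and >= 0", "rtquic_validation_error")
  }
  df <- dplyr::arrange(df, .data$well, .data$time_h)
  dup <- duplicated(df[, c("well", "time_h")])
  if (any(dup)) {
    i <- which(dup)[1]
    quic_abort(
      sprintf("duplicated reading for well %s at t = %g h",
              df$well[i], df$time_h[i]),
      "rtquic_validation_error"
    )
  }
  n_per_well <- table(df$well)
  if (any(n_per_well < 2)) {
    quic_abort(
      sprintf("well %s has fewer than 2 readings",
              names(n_per_well)[which(n_per_well < 2)[1]]),
      "rtquic_validation_error"
    )
  }
  class(df) <- c("quic_traces", class(df))
  df
}

#' Write traces to the canonical long CSV
#'
#' Values are written as decimal text with 6 significant digits, so a
#' write-then-read round trip reproduces the stored representation exactly.
#'
#' @param traces A `quic_traces` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  traces <- as_quic_traces(traces)
  out <- data.frame(
    well = traces$well,
    time_h = formatC(signif(traces$time_h, 6), format = "g", digits = 6),
    rfu = formatC(signif(traces$rfu, 6), format = "g", digits = 6)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a plate map
#'
#' The plate map links each well to a subject, a sample (one sample is one
#' specimen from one subject, run in replicate wells), the specimen type
#' (nasal swab at the agger nasi `NS_AN`, at the middle turbinate `NS_MT`,
#' or cerebrospinal fluid `CSF`), the clinical diagnosis group, and the
#' replicate index within the sample. Specimen and diagnosis tokens are
#' parsed case-insensitively.
#'
#' @param path CSV with header `well,subject,sample,specimen,diagnosis,replicate`
#'   and an optional `center` column.
#' @return A `quic_plate_map` tibble.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) {
    quic_abort(sprintf("plate map not found: %s", path), "rtquic_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_quic_plate_map(df)
}

#' Validate a plate map data frame
#'
#' @param df Data frame with columns `well`, `subject`, `sample`,
#'   `specimen`, `diagnosis`, `replicate` and optionally `center`.
#' @return A validated `quic_plate_map` tibble.
#' @export
as_quic_plate_map <- function(df) {
  required <- c("well", "subject", "sample", "specimen", "diagnosis",
                "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    quic_abort(
      sprintf("plate map is missing column(s): %s",
              paste(missing, collapse = ", ")),
      "rtquic_format_error"
    )
  }
  df <- tibble::as_tibble(df)
  if (!"center" %in% names(df)) df$center <- NA_character_
  df <- df[, c(required, "center")]
  df$well <- as.character(df$well)
  df$subject <- as.character(df$subject)
  df$sample <- as.character(df$sample)
  df$specimen <- parse_enum(df$specimen, SPECIMEN_LEVELS, "specimen")
  df$diagnosis <- parse_enum(df$diagnosis, DIAGNOSIS_LEVELS, "diagnosis")
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$well)) {
    quic_abort(
      sprintf("duplicated well in plate map: %s",
              df$well[duplicated(df$well)][1]),
      "rtquic_validation_error"
    )
  }
  if (any(df$replicate < 1)) {
    quic_abort("replicate indices must be >= 1", "rtquic_validation_error")
  }
  dup_rep <- duplicated(df[, c("sample", "replicate")])
  if (any(dup_rep)) {
    quic_abort(
      sprintf("duplicated replicate index within sample %s",
              df$sample[dup_rep][1]),
      "rtquic_validation_error"
    )
  }
  class(df) <- c("quic_plate_map", class(df))
  df
}

#' Write a plate map to CSV
#' @param plate_map A `quic_plate_map` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(plate_map, path) {
  out <- as.data.frame(plate_map)
  out$specimen <- as.character(out$specimen)
  out$diagnosis <- as.character(out$diagnosis)
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Write sample-level positivity calls to CSV
#'
#' One row per sample: identity, replicate counts, the positive/negative
#' call, the lag times of the replicates that crossed the threshold
#' (semicolon-joined, empty when none crossed), and the mean normalized
#' fluorescence at the cutoff time.
#'
#' @param calls A `quic_calls` tibble as produced by [call_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0) {
    quic_abort("refusing to write an empty calls table", "rtquic_validation_error")
  }
  out <- data.frame(
    sample = calls$sample,
    subject = calls$subject,
    specimen = as.character(calls$specimen),
    diagnosis = as.character(calls$diagnosis),
    n_replicates = calls$n_replicates,
    n_positive_replicates = calls$n_positive_replicates,
    call = calls$call,
    lag_times = vapply(
      calls$lag_times,
      function(l) paste(formatC(l, format = "g", digits = 6), collapse = ";"),
      character(1)
    ),
    endpoint_mean_percent = calls$endpoint_mean_percent
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a calls CSV written by [write_calls()]
#' @param path Path to a calls CSV.
#' @return A `quic_calls` tibble.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) {
    quic_abort(sprintf("calls file not found: %s", path), "rtquic_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(lag_times = readr::col_character()))
  df$specimen <- parse_enum(df$specimen, SPECIMEN_LEVELS, "specimen")
  df$diagnosis <- parse_enum(df$diagnosis, DIAGNOSIS_LEVELS, "diagnosis")
  df$lag_times <- lapply(df$lag_times, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";")[[1]])
  })
  class(df) <- c("quic_calls", class(df))
  df
}
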