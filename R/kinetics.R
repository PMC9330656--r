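#' Configuration for trace processing and positivity calling
#'
#' Bundles every tunable of the calling procedure. Defaults implement the
#' published protocol: a 10-h sliding baseline window, a noise threshold of
#' mean + 3 SD over the 15-17 h incubation window, a 20% positivity line on
#' percent-of-maximum normalized fluorescence, an 80-h cutoff, and a
#' sample call requiring at least 2 of 4 replicate wells to cross.
#'
#' Two threshold definitions coexist in practice: the fixed 20%-of-maximum
#' line and the run-specific noise floor. `threshold_mode` selects which is
#' enforced; the default `"max_of_both"` requires a replicate to exceed
#' both, protecting low-signal runs where the 20% line alone would sit
#' inside the noise band.
#'
#' @param baseline_window_h Width in hours of the sliding window over which
#'   the baseline is the minimum mean fluorescence.
#' @param noise_window_h Two-element vector, the closed incubation-time
#'   interval (hours) whose readings define the noise floor.
#' @param noise_sd_multiplier Number of SDs added to the noise-window mean.
#' @param percent_threshold Fixed positivity line, percent of the
#'   normalization maximum.
#' @param cutoff_time_h Readings after this time are ignored; a replicate
#'   crossing only later is negative.
#' @param min_positive_replicates Crossed replicates required for a
#'   positive sample call (capped at the number of replicates available).
#' @param expected_replicates Replicates normally run per sample; samples
#'   with fewer are flagged but still called (at least 2 required).
#' @param threshold_mode `"max_of_both"`, `"percent_only"` or `"noise_only"`.
#' @param normalization_scope `"run"` (default; the 20% criterion retains
#'   discriminative meaning against the run-wide maximum) or `"sample"`
#'   (each sample self-normalizes to 100%, as in per-sample trace figures).
#' @return A `quic_config` list.
#' @export
calling_config <- function(baseline_window_h = 10,
                           noise_window_h = c(15, 17),
                           noise_sd_multiplier = 3,
                           percent_threshold = 20,
                           cutoff_time_h = 80,
                           min_positive_replicates = 2,
                           expected_replicates = 4,
                           threshold_mode = c("max_of_both", "percent_only",
                                              "noise_only"),
                           normalization_scope = c("run", "sample")) {
  threshold_mode <- rlang::arg_match(threshold_mode)
  normalization_scope <- rlang::arg_match(normalization_scope)
  stopifnot(
    baseline_window_h > 0,
    length(noise_window_h) == 2, noise_window_h[1] < noise_window_h[2],
    noise_sd_multiplier >= 0,
    percent_threshold > 0, percent_threshold < 100,
    cutoff_time_h > 0,
    min_positive_replicates >= 1,
    min_positive_replicates <= expected_replicates
  )
  structure(
    list(
      baseline_window_h = baseline_window_h,
      noise_window_h = as.numeric(noise_window_h),
      noise_sd_multiplier = noise_sd_multiplier,
      percent_threshold = percent_threshold,
      cutoff_time_h = cutoff_time_h,
      min_positive_replicates = as.integer(min_positive_replicates),
      expected_replicates = as.integer(expected_replicates),
      threshold_mode = threshold_mode,
      normalization_scope = normalization_scope
    ),
    class = "quic_config"
  )
}

#' Find the baseline window of a mean fluorescence trace
#'
#' Scans every contiguous reading window of the given duration and returns
#' the one minimizing the mean rfu; ties break to the earliest window. The
#' baseline value is the mean rfu over that window. When the trace is
#' shorter than the window the full span is used and flagged.
#'
#' @param times Reading times in hours, strictly increasing.
#' @param values Mean rfu across the replicates of a sample, same length.
#' @param width_h Window duration in hours (default 10).
#' @return A list with `t_start`, `t_end`, `baseline` and `clipped`.
#' @export
find_baseline_window <- function(times, values, width_h = 10) {
  n <- length(times)
  if (n < 2 || length(values) != n) {
    quic_abort("baseline window needs >= 2 readings", "rtquic_validation_error")
  }
  span <- times[n] - times[1]
  if (span < width_h) {
    return(list(t_start = times[1], t_end = times[n],
                baseline = mean(values), clipped = TRUE))
  }
  # window starting at reading i covers readings with t in [t_i, t_i + width]
  starts <- which(times + width_h <= times[n] + 1e-9)
  ends <- findInterval(times[starts] + width_h + 1e-9, times)
  csum <- c(0, cumsum(values))
  means <- (csum[ends + 1] - csum[starts]) / (ends - starts + 1)
  best <- starts[which.min(means)] # which.min takes the first (earliest) tie
  best_end <- ends[which(starts == best)]
  list(t_start = times[best], t_end = times[best_end],
       baseline = min(means), clipped = FALSE)
}

#' Baseline-adjust and normalize the traces of one run
#'
#' For each sample, the baseline is computed on the mean-of-replicates
#' trace with [find_baseline_window()] and subtracted from every replicate
#' reading; negative adjusted values are floored at 0 so percent values
#' stay in \[0, 100\]. Adjusted values are then expressed as percent of the
#' normalization maximum: the largest baseline-adjusted reading over the
#' whole run (`scope = "run"`, default) or over each sample
#' (`scope = "sample"`).
#'
#' @param traces A `quic_traces` tibble (one run, i.e. one plate).
#' @param plate_map A `quic_plate_map` covering the wells in `traces`.
#' @param config A [calling_config()].
#' @param ignore_unmapped If `FALSE` (default), wells present in the traces
#'   but absent from the plate map are an error; if `TRUE` they are dropped
#'   with a warning. Silent dropping would hide plate-layout mistakes.
#' @return A `quic_normalized` object: list with `data` (tibble `well`,
#'   `sample`, `subject`, `specimen`, `diagnosis`, `replicate`, `time_h`,
#'   `adjusted`, `percent`), `baselines` (per-sample window and value),
#'   `normalization_max`, `scope` and `config`.
#' @export
normalize_traces <- function(traces, plate_map, config = calling_config(),
                             ignore_unmapped = FALSE) {
  traces <- as_quic_traces(traces)
  plate_map <- as_quic_plate_map(plate_map)

  unmapped <- setdiff(unique(traces$well), plate_map$well)
  if (length(unmapped) > 0) {
    if (!ignore_unmapped) {
      quic_abort(
        sprintf("unmapped well(s) in traces: %s",
                paste(unmapped, collapse = ", ")),
        "rtquic_validation_error"
      )
    }
    rlang::warn(sprintf("dropping %d unmapped well(s)", length(unmapped)))
    traces <- traces[!traces$well %in% unmapped, ]
  }

  joined <- dplyr::inner_join(traces, plate_map, by = "well")
  pieces <- split(joined, joined$sample)
  out <- vector("list", length(pieces))
  baselines <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    d <- pieces[[i]]
    # replicates of one sample must share the reading grid
    grids <- split(d$time_h, d$well)
    ref <- grids[[1]]
    same <- all(vapply(grids, function(g) {
      length(g) == length(ref) && all(abs(g - ref) < 1e-9)
    }, logical(1)))
    if (!same) {
      quic_abort(
        sprintf("replicates of sample %s are not on a common time grid",
                d$sample[1]),
        "rtquic_validation_error"
      )
    }
    mean_rfu <- rowsum(d$rfu, match(d$time_h, ref))[, 1] / length(grids)
    bw <- find_baseline_window(ref, mean_rfu, config$baseline_window_h)
    d$adjusted <- pmax(d$rfu - bw$baseline, 0)
    out[[i]] <- d
    baselines[[i]] <- tibble::tibble(
      sample = d$sample[1], t_start = bw$t_start, t_end = bw$t_end,
      baseline = bw$baseline, clipped = bw$clipped
    )
  }
  data <- dplyr::bind_rows(out)
  baselines <- dplyr::bind_rows(baselines)

  if (config$normalization_scope == "run") {
    norm_max <- max(data$adjusted)
    if (norm_max <= 0) {
      quic_abort("no signal in run: normalization maximum is not positive",
                 "rtquic_validation_error")
    }
    data$percent <- 100 * data$adjusted / norm_max
  } else {
    data <- dplyr::group_by(data, .data$sample)
    data <- dplyr::mutate(data, .max = max(.data$adjusted))
    data <- dplyr::ungroup(data)
    if (any(data$.max <= 0)) {
      quic_abort("no signal in run: normalization maximum is not positive",
                 "rtquic_validation_error")
    }
    data$percent <- 100 * data$adjusted / data$.max
    norm_max <- stats::setNames(
      tapply(data$.max, data$sample, `[`, 1), NULL
    )
    data$.max <- NULL
  }
  data <- dplyr::select(
    data, "well", "sample", "subject", "specimen", "diagnosis",
    "replicate", "time_h", "adjusted", "percent"
  )
  structure(
    list(data = data, baselines = baselines, normalization_max = norm_max,
         scope = config$normalization_scope, config = config),
    class = "quic_normalized"
  )
}

#' Noise-floor threshold of a normalized run
#'
#' Mean of all replicate normalized values whose reading time falls in the
#' closed noise window, plus `sd_multiplier` sample standard deviations
#' (denominator n - 1).
#'
#' @param normalized A `quic_normalized` object.
#' @param window_h Closed time interval in hours, default from the config.
#' @param sd_multiplier Default from the config.
#' @return Threshold in percent units.
#' @export
noise_threshold <- function(normalized,
                            window_h = normalized$config$noise_window_h,
                            sd_multiplier = normalized$config$noise_sd_multiplier) {
  v <- normalized$data$percent[
    normalized$data$time_h >= window_h[1] - 1e-9 &
      normalized$data$time_h <= window_h[2] + 1e-9
  ]
  if (length(v) < 2) {
    quic_abort(
      sprintf("fewer than 2 readings in the noise window [%g, %g] h",
              window_h[1], window_h[2]),
      "rtquic_validation_error"
    )
  }
  mean(v) + sd_multiplier * stats::sd(v)
}

# Effective threshold under the configured mode.
effective_threshold <- function(config, noise_thr) {
  switch(config$threshold_mode,
    percent_only = config$percent_threshold,
    noise_only = noise_thr,
    max_of_both = max(config$percent_threshold, noise_thr)
  )
}

#' Call replicates and samples of a normalized run
#'
#' A replicate is crossed when any reading at or before the cutoff time
#' reaches the effective threshold; its lag time is the time of the first
#' such reading (no interpolation — lag resolution is the reading
#' interval). A sample is positive when at least
#' `min(min_positive_replicates, k)` of its k replicates crossed; samples
#' with fewer than 2 replicates are an error. The endpoint summary is the
#' mean across replicates of the last reading at or before the cutoff.
#'
#' @param normalized A `quic_normalized` object.
#' @param config A [calling_config()]; defaults to the one used for
#'   normalization.
#' @return A `quic_calls` tibble (one row per sample) with attributes
#'   `replicates` (per-well detail) and `threshold` (the effective
#'   threshold applied, in percent).
#' @export
call_samples <- function(normalized, config = normalized$config) {
  noise_thr <- if (config$threshold_mode == "percent_only") {
    NA_real_
  } else {
    noise_threshold(normalized, config$noise_window_h,
                    config$noise_sd_multiplier)
  }
  thr <- effective_threshold(config, noise_thr)
  cutoff <- config$cutoff_time_h

  d <- normalized$data[normalized$data$time_h <= cutoff + 1e-9, ]
  if (nrow(d) == 0) {
    quic_abort("no readings at or before the cutoff time",
               "rtquic_validation_error")
  }

  per_rep <- lapply(split(d, d$well), function(w) {
    w <- w[order(w$time_h), ]
    hit <- which(w$percent >= thr)
    tibble::tibble(
      well = w$well[1], sample = w$sample[1], replicate = w$replicate[1],
      crossed = length(hit) > 0,
      lag_time_h = if (length(hit) > 0) w$time_h[hit[1]] else NA_real_,
      threshold_used = thr,
      endpoint_percent = w$percent[nrow(w)]
    )
  })
  reps <- dplyr::bind_rows(per_rep)

  ident <- dplyr::distinct(
    normalized$data,
    .data$sample, .data$subject, .data$specimen, .data$diagnosis
  )
  per_sample <- lapply(split(reps, reps$sample), function(r) {
    k <- nrow(r)
    if (k < 2) {
      quic_abort(
        sprintf("insufficient replicates for sample %s (%d; need >= 2)",
                r$sample[1], k),
        "rtquic_validation_error"
      )
    }
    need <- min(config$min_positive_replicates, k)
    n_pos <- sum(r$crossed)
    tibble::tibble(
      sample = r$sample[1],
      n_replicates = k,
      n_positive_replicates = n_pos,
      call = if (n_pos >= need) "positive" else "negative",
      lag_times = list(sort(r$lag_time_h[r$crossed])),
      endpoint_mean_percent = mean(r$endpoint_percent),
      underreplicated = k < config$expected_replicates
    )
  })
  calls <- dplyr::bind_rows(per_sample)
  calls <- dplyr::left_join(ident, calls, by = "sample")
  calls <- calls[order(calls$sample), ]
  class(calls) <- c("quic_calls", class(calls))
  attr(calls, "replicates") <- reps
  attr(calls, "threshold") <- thr
  attr(calls, "noise_threshold") <- noise_thr
  calls
}

#' Kinetic summaries for a group of samples
#'
#' Reproduces the figure-style group summaries: mean normalized endpoint
#' fluorescence of the positive samples, mean lag time of the replicates
#' that crossed, and the pointwise mean and SD trace over the positive
#' samples' per-sample mean traces.
#'
#' @param calls A `quic_calls` tibble.
#' @param normalized The `quic_normalized` object the calls came from.
#' @param samples Character vector of sample ids defining the group.
#' @return List with `n_samples`, `n_positive`, `mean_endpoint_percent`,
#'   `mean_lag_h`, and `trace` (tibble `time_h`, `mean_percent`,
#'   `sd_percent`).
#' @export
summarize_group_kinetics <- function(calls, normalized, samples) {
  grp <- calls[calls$sample %in% samples, ]
  if (nrow(grp) == 0) {
    quic_abort("empty group", "rtquic_validation_error")
  }
  pos <- grp[grp$call == "positive", ]
  lags <- unlist(pos$lag_times)
  d <- normalized$data[normalized$data$sample %in% pos$sample, ]
  trace <- NULL
  if (nrow(d) > 0) {
    sample_means <- dplyr::summarise(
      dplyr::group_by(d, .data$sample, .data$time_h),
      percent = mean(.data$percent), .groups = "drop"
    )
    trace <- dplyr::summarise(
      dplyr::group_by(sample_means, .data$time_h),
      mean_percent = mean(.data$percent),
      sd_percent = stats::sd(.data$percent),
      .groups = "drop"
    )
  }
  list(
    n_samples = nrow(grp),
    n_positive = nrow(pos),
    mean_endpoint_percent = if (nrow(pos) > 0) {
      mean(pos$endpoint_mean_percent)
    } else {
      NA_real_
    },
    mean_lag_h = if (length(lags) > 0) mean(lags) else NA_real_,
    trace = trace
  )
}
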