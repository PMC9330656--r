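#' Kinetic parameters for one simulated group
#'
#' Describes the seeding kinetics of a cohort group. Converting replicates
#' follow logistic (sigmoid) growth — the simplest shape matching the
#' lag-then-plateau traces of seed-amplification assays — on top of a flat
#' baseline with Gaussian reader noise; non-converting replicates are
#' baseline plus noise only. The lag is parameterized directly as the
#' analytic time at which the trace crosses 20% of the nominal run
#' maximum, so simulated truth and pipeline lag estimates are directly
#' comparable.
#'
#' @param lag_mean_h,lag_sd_h Normal distribution of the threshold-crossing
#'   lag, hours.
#' @param plateau_mean,plateau_sd Normal distribution of the plateau, as a
#'   fraction of the nominal run maximum; draws are clipped to
#'   \[0.25, 1\] so every converting replicate can cross the 20% line.
#' @param growth_rate Logistic growth rate, per hour.
#' @param conversion_prob Probability that a replicate of a seeding sample
#'   converts.
#' @param baseline_rfu Flat baseline fluorescence, rfu.
#' @param noise_sd_rfu SD of the additive Gaussian reader noise, rfu.
#' @param spontaneous_prob Probability that a replicate of a non-seeding
#'   sample converts anyway (spontaneous substrate conversion).
#' @return A `quic_group_params` list.
#' @export
group_params <- function(lag_mean_h, lag_sd_h, plateau_mean, plateau_sd,
                         growth_rate = 0.8, conversion_prob = 1,
                         baseline_rfu = 800, noise_sd_rfu = 20,
                         spontaneous_prob = 0) {
  stopifnot(
    lag_mean_h > 0, lag_sd_h >= 0,
    plateau_mean > 0, plateau_mean <= 1, plateau_sd >= 0,
    growth_rate > 0,
    conversion_prob >= 0, conversion_prob <= 1,
    baseline_rfu >= 0, noise_sd_rfu >= 0,
    spontaneous_prob >= 0, spontaneous_prob <= 1
  )
  structure(
    list(lag_mean_h = lag_mean_h, lag_sd_h = lag_sd_h,
         plateau_mean = plateau_mean, plateau_sd = plateau_sd,
         growth_rate = growth_rate, conversion_prob = conversion_prob,
         baseline_rfu = baseline_rfu, noise_sd_rfu = noise_sd_rfu,
         spontaneous_prob = spontaneous_prob),
    class = "quic_group_params"
  )
}

#' Define one group of a simulated cohort
#'
#' @param name Group name, unique within a cohort; used in sample ids.
#' @param specimen One of `NS_AN`, `NS_MT`, `CSF`.
#' @param diagnosis One of `PD`, `NON_PD`, `CONTROL`.
#' @param n_subjects Number of subjects (one sample each).
#' @param seeder Whether samples in this group carry seeding activity
#'   (replicates then convert with `conversion_prob`; otherwise with
#'   `spontaneous_prob`).
#' @param params A [group_params()] object.
#' @return A `quic_cohort_group` list.
#' @export
cohort_group <- function(name, specimen, diagnosis, n_subjects, seeder,
                         params) {
  stopifnot(n_subjects >= 1, inherits(params, "quic_group_params"),
            is.logical(seeder))
  structure(
    list(name = as.character(name),
         specimen = as.character(parse_enum(specimen, SPECIMEN_LEVELS,
                                            "specimen")),
         diagnosis = as.character(parse_enum(diagnosis, DIAGNOSIS_LEVELS,
                                             "diagnosis")),
         n_subjects = as.integer(n_subjects), seeder = seeder,
         params = params),
    class = "quic_cohort_group"
  )
}

#' Configuration of a simulated cohort
#'
#' @param groups List of [cohort_group()] objects with unique names.
#' @param replicates_per_sample Replicate wells per sample (default 4).
#' @param reading_interval_h Reading interval, hours (default 0.75, i.e.
#'   one reading every 45 minutes).
#' @param total_time_h Run duration, hours (default 90, comfortably past
#'   the standard 80-h calling cutoff).
#' @param rfu_scale Nominal run-maximum fluorescence in rfu; plateaus are
#'   fractions of this scale.
#' @return A `quic_synth_config` list.
#' @export
cohort_config <- function(groups, replicates_per_sample = 4,
                          reading_interval_h = 0.75, total_time_h = 90,
                          rfu_scale = 10000) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "quic_cohort_group")),
            replicates_per_sample >= 1, reading_interval_h > 0,
            total_time_h > 0, rfu_scale > 0)
  names <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(names)) {
    quic_abort("duplicate group names in cohort config",
               "rtquic_validation_error")
  }
  structure(
    list(groups = groups,
         replicates_per_sample = as.integer(replicates_per_sample),
         reading_interval_h = reading_interval_h,
         total_time_h = total_time_h, rfu_scale = rfu_scale),
    class = "quic_synth_config"
  )
}

# Fraction of the nominal run maximum at which the simulated lag is
# defined; matches the default 20% calling threshold.
CROSSING_FRACTION <- 0.2

# Draw per-replicate kinetic quantities for one group. All draws happen
# for every replicate regardless of conversion status, so the RNG stream
# (and hence the whole cohort) is reproducible from the seed alone.
draw_group <- function(group, n_rep) {
  p <- group$params
  conv_p <- if (group$seeder) p$conversion_prob else p$spontaneous_prob
  converts <- stats::runif(n_rep) < conv_p
  lag <- pmax(stats::rnorm(n_rep, p$lag_mean_h, p$lag_sd_h), 2)
  plateau <- pmin(pmax(stats::rnorm(n_rep, p$plateau_mean, p$plateau_sd),
                       0.25), 1)
  list(converts = converts, lag = lag, plateau = plateau)
}

# Noiseless converted signal (rfu above baseline) on the reading grid.
# One column per replicate; zero columns for non-converting replicates.
signal_matrix <- function(times, converts, lag, plateau, growth_rate,
                          rfu_scale) {
  n_rep <- length(converts)
  sig <- matrix(0, nrow = length(times), ncol = n_rep)
  if (any(converts)) {
    plateau_rfu <- plateau[converts] * rfu_scale
    thr_rfu <- CROSSING_FRACTION * rfu_scale
    # t50 chosen so the sigmoid crosses thr_rfu exactly at the drawn lag
    t50 <- lag[converts] + log(plateau_rfu / thr_rfu - 1) / growth_rate
    sig[, converts] <- stats::plogis(growth_rate * outer(times, t50, "-")) *
      rep(plateau_rfu, each = length(times))
  }
  sig
}

#' Simulate one replicate trace
#'
#' Single-replicate version of the cohort generator, using the current RNG
#' state for the noise draw. Converting replicates get a logistic rise
#' whose analytic crossing of 20% of `rfu_scale` equals `lag_h`;
#' non-converting replicates are baseline plus noise. Values are floored
#' at 0.
#'
#' @param params A [group_params()] object.
#' @param converts Whether this replicate converts.
#' @param lag_h,plateau Kinetic quantities for a converting replicate
#'   (defaults: the group means).
#' @param times Reading grid in hours.
#' @param rfu_scale Nominal run maximum, rfu.
#' @param well Well id for the returned trace.
#' @return A `quic_traces` tibble for one well.
#' @export
simulate_replicate <- function(params, converts, lag_h = params$lag_mean_h,
                               plateau = params$plateau_mean,
                               times = seq(0, 90, by = 0.75),
                               rfu_scale = 10000, well = "W00001") {
  sig <- signal_matrix(times, converts, lag_h, plateau, params$growth_rate,
                       rfu_scale)[, 1]
  noise <- if (params$noise_sd_rfu > 0) {
    stats::rnorm(length(times), 0, params$noise_sd_rfu)
  } else {
    0
  }
  as_quic_traces(tibble::tibble(
    well = well, time_h = times,
    rfu = pmax(params$baseline_rfu + sig + noise, 0)
  ))
}

#' Simulate a plate-reader cohort
#'
#' Generates fluorescence traces, a plate map and a truth table for a
#' synthetic cohort. Per subject one sample; per sample
#' `replicates_per_sample` replicate wells. Whether a replicate converts
#' is Bernoulli with the group's conversion probability (seeding samples)
#' or spontaneous-conversion probability (non-seeding samples). The truth
#' table records, before noise is added, each replicate's conversion flag
#' and the first reading time at which its noiseless signal reaches 20% of
#' the realized run maximum — the quantity the calling pipeline estimates.
#'
#' All randomness comes from R's Mersenne-Twister stream seeded once with
#' `seed`; identical config and seed reproduce the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `quic_cohort` list: `traces` (`quic_traces`), `plate_map`
#'   (`quic_plate_map`), `truth` (tibble `sample`, `well`, `replicate`,
#'   `true_status`, `converts`, `true_crossing_h`), `times`, `config`,
#'   `seed`.
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "quic_synth_config"))
  set.seed(seed, kind = "Mersenne-Twister")
  times <- seq(0, config$total_time_h, by = config$reading_interval_h)
  reps <- config$replicates_per_sample

  draws <- lapply(config$groups, function(g) {
    draw_group(g, g$n_subjects * reps)
  })
  signals <- lapply(seq_along(config$groups), function(i) {
    g <- config$groups[[i]]
    d <- draws[[i]]
    signal_matrix(times, d$converts, d$lag, d$plateau,
                  g$params$growth_rate, config$rfu_scale)
  })
  run_max <- max(vapply(signals, max, numeric(1)))
  thr <- CROSSING_FRACTION * run_max

  well_counter <- 0L
  traces <- vector("list", length(config$groups))
  maps <- vector("list", length(config$groups))
  truths <- vector("list", length(config$groups))
  for (i in seq_along(config$groups)) {
    g <- config$groups[[i]]
    d <- draws[[i]]
    sig <- signals[[i]]
    n_rep <- g$n_subjects * reps
    noise <- if (g$params$noise_sd_rfu > 0) {
      matrix(stats::rnorm(length(times) * n_rep, 0, g$params$noise_sd_rfu),
             nrow = length(times))
    } else {
      0
    }
    rfu <- pmax(g$params$baseline_rfu + sig + noise, 0)

    wells <- sprintf("W%05d", well_counter + seq_len(n_rep))
    well_counter <- well_counter + n_rep
    subjects <- sprintf("%s_%03d", g$name, rep(seq_len(g$n_subjects),
                                               each = reps))
    samples <- subjects
    repl <- rep(seq_len(reps), g$n_subjects)

    traces[[i]] <- tibble::tibble(
      well = rep(wells, each = length(times)),
      time_h = rep(times, times = n_rep),
      rfu = as.vector(rfu)
    )
    maps[[i]] <- tibble::tibble(
      well = wells, subject = subjects, sample = samples,
      specimen = g$specimen, diagnosis = g$diagnosis, replicate = repl,
      center = NA_character_
    )
    # first grid reading at/above 20% of the realized run maximum
    if (run_max > 0) {
      below <- colSums(sig < thr)
      crossing <- ifelse(d$converts & below < length(times),
                         times[pmin(below + 1, length(times))], NA_real_)
    } else {
      crossing <- rep(NA_real_, n_rep)
    }
    truths[[i]] <- tibble::tibble(
      sample = samples, well = wells, replicate = repl,
      true_status = if (g$seeder) "seeder" else "non-seeder",
      converts = d$converts,
      true_crossing_h = crossing
    )
  }
  structure(
    list(
      traces = as_quic_traces(dplyr::bind_rows(traces)),
      plate_map = as_quic_plate_map(dplyr::bind_rows(maps)),
      truth = dplyr::bind_rows(truths),
      times = times,
      config = config,
      seed = seed
    ),
    class = "quic_cohort"
  )
}

#' Sample positivity implied by a per-replicate conversion probability
#'
#' Probability that at least `min_positive` of `n_replicates` independent
#' replicates convert — the binomial tail that links replicate-level
#' conversion to the sample-level call rate under the 2-of-4 rule.
#'
#' @param p Per-replicate conversion probability.
#' @param n_replicates Replicates per sample.
#' @param min_positive Crossed replicates required for a positive call.
#' @return Sample-level positivity probability.
#' @export
sample_positivity_prob <- function(p, n_replicates = 4, min_positive = 2) {
  1 - stats::pbinom(min_positive - 1, n_replicates, p)
}

#' Back-solve the per-replicate conversion probability for a target rate
#'
#' Inverts [sample_positivity_prob()] by root finding: the per-replicate
#' probability under which the expected sample positivity equals `target`.
#' Published studies report sample-level rates only, so the replicate-level
#' probability is under-determined; this is the unique solution under the
#' independent-replicates binomial model.
#'
#' @param target Target sample-level positivity in (0, 1).
#' @param n_replicates,min_positive As in [sample_positivity_prob()].
#' @return Per-replicate conversion probability.
#' @export
replicate_conversion_prob <- function(target, n_replicates = 4,
                                      min_positive = 2) {
  stopifnot(target > 0, target < 1)
  stats::uniroot(
    function(p) sample_positivity_prob(p, n_replicates, min_positive) - target,
    interval = c(1e-9, 1 - 1e-9), tol = 1e-12
  )$root
}

#' Cohort configuration calibrated to published first-round rates
#'
#' A packaged [cohort_config()] whose expected sample-level call rates
#' match the observed first-round rates of the nasal-swab study this
#' package's procedure implements: agger nasi PD 84%, middle turbinate PD
#' 45%, non-PD 10%, with group mean lags of 41 h (AN) and 47 h (MT) and
#' endpoint plateaus around 80% and 57% of the run maximum. Per-replicate
#' conversion probabilities are back-solved from the sample-level targets
#' through the at-least-2-of-4 binomial tail. This is a calibration of the
#' generator to summary statistics, not a reproduction of raw data.
#'
#' @param n_an_pd,n_mt_pd,n_non_pd_an,n_non_pd_mt Group sizes; defaults
#'   mirror the first-round cohort (32 / 11 / 14 / 15).
#' @param an_rate,mt_rate,non_pd_rate Target sample positivity rates.
#' @return A `quic_synth_config`.
#' @export
calibrated_cohort_config <- function(n_an_pd = 32, n_mt_pd = 11,
                                     n_non_pd_an = 14, n_non_pd_mt = 15,
                                     an_rate = 0.84, mt_rate = 0.45,
                                     non_pd_rate = 0.10) {
  p_an <- replicate_conversion_prob(an_rate)
  p_mt <- replicate_conversion_prob(mt_rate)
  p_spont <- replicate_conversion_prob(non_pd_rate)
  negative_params <- group_params(
    lag_mean_h = 55, lag_sd_h = 8, plateau_mean = 0.5, plateau_sd = 0.1,
    conversion_prob = 0, spontaneous_prob = p_spont
  )
  cohort_config(list(
    cohort_group("an_pd", "NS_AN", "PD", n_an_pd, seeder = TRUE,
                 group_params(lag_mean_h = 41, lag_sd_h = 4,
                              plateau_mean = 0.80, plateau_sd = 0.08,
                              conversion_prob = p_an)),
    cohort_group("mt_pd", "NS_MT", "PD", n_mt_pd, seeder = TRUE,
                 group_params(lag_mean_h = 47, lag_sd_h = 5,
                              plateau_mean = 0.57, plateau_sd = 0.08,
                              conversion_prob = p_mt)),
    cohort_group("non_pd_an", "NS_AN", "NON_PD", n_non_pd_an,
                 seeder = FALSE, negative_params),
    cohort_group("non_pd_mt", "NS_MT", "NON_PD", n_non_pd_mt,
                 seeder = FALSE, negative_params)
  ))
}

#' Write a simulated cohort to CSV files
#'
#' @param cohort A `quic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed); writes `traces.csv`,
#'   `plate_map.csv`, `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_traces(cohort$traces, file.path(dir, "traces.csv"))
  write_plate_map(cohort$plate_map, file.path(dir, "plate_map.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
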