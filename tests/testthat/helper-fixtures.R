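# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal long-format trace tibble for hand-built wells.
make_traces <- function(...) {
  wells <- list(...)
  as_quic_traces(dplyr::bind_rows(lapply(names(wells), function(w) {
    tibble::tibble(well = w,
                   time_h = wells[[w]]$time_h,
                   rfu = wells[[w]]$rfu)
  })))
}

# Plate map for n_samples samples x n_reps replicate wells, wells named
# W<k>, samples S<j>.
make_map <- function(n_samples, n_reps = 4, specimen = "NS_AN",
                     diagnosis = "PD") {
  k <- n_samples * n_reps
  as_quic_plate_map(tibble::tibble(
    well = paste0("W", seq_len(k)),
    subject = rep(paste0("SUBJ", seq_len(n_samples)), each = n_reps),
    sample = rep(paste0("S", seq_len(n_samples)), each = n_reps),
    specimen = specimen,
    diagnosis = diagnosis,
    replicate = rep(seq_len(n_reps), n_samples)
  ))
}

# Deterministic sigmoid trace in rfu.
sigmoid_rfu <- function(times, baseline, plateau_rfu, t50, rate = 0.8) {
  baseline + plateau_rfu * stats::plogis(rate * (times - t50))
}

# Brute-force baseline-window oracle: naive scan over every start reading,
# averaging all readings with t in [t_start, t_start + width].
baseline_oracle <- function(times, values, width) {
  n <- length(times)
  if (times[n] - times[1] < width) {
    return(list(t_start = times[1], t_end = times[n],
                baseline = mean(values)))
  }
  best <- NULL
  for (i in seq_len(n)) {
    if (times[i] + width > times[n] + 1e-9) break
    in_win <- times >= times[i] - 1e-9 & times <= times[i] + width + 1e-9
    m <- mean(values[in_win])
    if (is.null(best) || m < best$baseline - 1e-12) {
      best <- list(t_start = times[i], t_end = max(times[in_win]),
                   baseline = m)
    }
  }
  best
}

# Independent Fisher oracle: hypergeometric probabilities from binomial
# coefficients (not dhyper), point-probability two-sided convention.
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[support == a]
  total <- 0
  for (i in seq_along(support)) {
    if (probs[i] <= p_obs * (1 + 1e-7)) total <- total + probs[i]
  }
  total
}

# Random noisy run: one ramping control sample plus flat samples, used by
# the property tests.
random_run <- function(n_samples = 3, n_reps = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, 90, by = 0.75)
  map <- make_map(n_samples, n_reps)
  rows <- lapply(seq_len(nrow(map)), function(i) {
    lag <- stats::runif(1, 20, 75)
    plateau <- stats::runif(1, 2500, 10000)
    converting <- stats::runif(1) < 0.5
    rfu <- 800 + stats::rnorm(length(times), 0, 20) +
      if (converting) plateau * stats::plogis(0.8 * (times - lag)) else 0
    tibble::tibble(well = map$well[i], time_h = times, rfu = pmax(rfu, 0))
  })
  list(traces = as_quic_traces(dplyr::bind_rows(rows)), map = map)
}
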