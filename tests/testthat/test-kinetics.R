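times_std <- seq(0, 90, by = 0.75)

test_that("baseline window finds the lowest 10-h window with earliest tie-break", {
  # monotone increasing trace: lowest window starts at t = 0
  mono <- find_baseline_window(seq(0, 80, by = 0.8), seq(0, 100, by = 1))
  expect_equal(mono$t_start, 0)
  expect_false(mono$clipped)

  # constant trace: all windows tie, earliest wins
  const <- find_baseline_window(times_std, rep(500, length(times_std)))
  expect_equal(const$t_start, 0)
  expect_equal(const$t_end, 9.75)  # last reading inside [0, 10] on the 45-min grid
  expect_equal(const$baseline, 500)

  # shorter than the window: full span, flagged
  clip <- find_baseline_window(c(0, 1, 2), c(5, 7, 9), width_h = 10)
  expect_true(clip$clipped)
  expect_equal(clip$baseline, 7)

  expect_error(find_baseline_window(1, 1), class = "rtquic_validation_error")
})

test_that("baseline of a noisy sigmoid matches the exhaustive window-scan oracle", {
  set.seed(101)
  rfu <- sigmoid_rfu(times_std, 800, 10000, t50 = 42) +
    rnorm(length(times_std), 0, 20)
  got <- find_baseline_window(times_std, rfu)
  oracle <- baseline_oracle(times_std, rfu, 10)
  expect_equal(got$t_start, oracle$t_start)
  expect_equal(got$baseline, oracle$baseline)
  expect_gt(got$baseline, 760)
  expect_lt(got$baseline, 840)
})

test_that("baseline window equals exhaustive scan on random irregular traces", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    times <- sort(runif(n, 0, 100))
    times <- times[c(TRUE, diff(times) > 1e-6)]
    values <- runif(length(times), 0, 1000)
    width <- runif(1, 2, 30)
    got <- find_baseline_window(times, values, width)
    oracle <- baseline_oracle(times, values, width)
    expect_equal(got$t_start, oracle$t_start)
    expect_equal(got$baseline, oracle$baseline)
  }
})

test_that("normalization applies the floor rule and the chosen scope", {
  times <- seq(0, 20, by = 1)
  # sample A: baseline 100 plateau to 1100 adjusted 1000; reading dips to 80
  a_vals <- c(100, 80, rep(100, 9), rep(1100, 10))
  b_vals <- c(rep(100, 11), rep(600, 10))  # adjusted peak 500
  tr <- make_traces(
    W1 = list(time_h = times, rfu = a_vals),
    W2 = list(time_h = times, rfu = a_vals),
    W3 = list(time_h = times, rfu = b_vals),
    W4 = list(time_h = times, rfu = b_vals)
  )
  map <- make_map(2, n_reps = 2)
  cfg <- calling_config()
  norm_run <- normalize_traces(tr, map, cfg)
  a <- norm_run$data[norm_run$data$sample == "S1", ]
  b <- norm_run$data[norm_run$data$sample == "S2", ]
  # baseline for S1 is the lowest 10-h window mean (includes the 80 dip)
  expect_lt(norm_run$baselines$baseline[1], 100)
  # floor: the dip to 80 never goes negative
  expect_true(all(norm_run$data$percent >= 0))
  # run scope: S1 peaks at 100%, S2 at ~50%
  expect_equal(max(a$percent), 100)
  expect_equal(max(b$percent), 100 * max(b$adjusted) / max(a$adjusted))
  expect_lt(max(b$percent), 52)

  cfg_s <- calling_config(normalization_scope = "sample")
  norm_sample <- normalize_traces(tr, map, cfg_s)
  by_sample <- tapply(norm_sample$data$percent, norm_sample$data$sample, max)
  expect_true(all(abs(by_sample - 100) < 1e-9))
})

test_that("all-flat runs are rejected as signal-free", {
  times <- seq(0, 20, by = 1)
  tr <- make_traces(
    W1 = list(time_h = times, rfu = rep(100, 21)),
    W2 = list(time_h = times, rfu = rep(100, 21))
  )
  map <- make_map(1, n_reps = 2)
  expect_error(normalize_traces(tr, map, calling_config()),
               "no signal", class = "rtquic_validation_error")
})

test_that("unmapped wells are an error by default, droppable on request", {
  run <- random_run(n_samples = 1, seed = 3)
  extra <- tibble::tibble(well = "GHOST", time_h = c(0, 1), rfu = c(1, 2))
  tr <- as_quic_traces(dplyr::bind_rows(as.data.frame(run$traces), extra))
  expect_error(normalize_traces(tr, run$map, calling_config()),
               "unmapped", class = "rtquic_validation_error")
  expect_warning(
    norm <- normalize_traces(tr, run$map, calling_config(),
                             ignore_unmapped = TRUE),
    "unmapped"
  )
  expect_false("GHOST" %in% norm$data$well)
})

test_that("noise threshold matches its closed form", {
  # two readings inside [15, 17] per well, all with value 5 -> SD 0
  times <- c(seq(0, 14, by = 1), 15.5, 16.5, seq(18, 30, by = 1))
  base <- 100
  mk <- function(v1, v2) {
    c(rep(base, 15), base + v1, base + v2, rep(base, 12), base + 1000)
  }
  tr <- make_traces(
    W1 = list(time_h = times, rfu = mk(50, 50)),
    W2 = list(time_h = times, rfu = mk(50, 50))
  )
  map <- make_map(1, n_reps = 2)
  norm <- normalize_traces(tr, map, calling_config())
  # all four in-window adjusted values are 50 of max 1000 -> 5 percent, SD 0
  expect_equal(noise_threshold(norm), 5, tolerance = 1e-6)

  # in-window values {4, 6} percent -> 5 + 3 * sqrt(2)
  tr2 <- make_traces(W1 = list(time_h = times, rfu = mk(40, 60)))
  norm2 <- normalize_traces(tr2, make_map(1, n_reps = 1), calling_config())
  expect_equal(noise_threshold(norm2), 5 + 3 * sqrt(2), tolerance = 1e-6)
})

test_that("noise threshold of a noisy run is within 3 SE of generator moments", {
  # flat early baseline with a known +100 rfu offset and sigma = 10 noise
  # from t >= 12 h, co-plated with a deterministic control whose adjusted
  # maximum is exactly 9200: threshold ~= 100/9200 * (100 + 3 * 10)
  set.seed(404)
  sigma <- 10
  n_neg <- 20
  step <- ifelse(times_std >= 12, 100, 0)
  control <- 800 + ifelse(times_std >= 30,
                          9200 * stats::plogis(0.8 * (times_std - 50)), 0)
  negs <- lapply(seq_len(n_neg), function(i) {
    noise <- ifelse(times_std >= 12, rnorm(length(times_std), 0, sigma), 0)
    tibble::tibble(well = paste0("W", i), time_h = times_std,
                   rfu = 800 + step + noise)
  })
  tr <- as_quic_traces(dplyr::bind_rows(c(negs, list(
    tibble::tibble(well = paste0("W", n_neg + 1), time_h = times_std,
                   rfu = control),
    tibble::tibble(well = paste0("W", n_neg + 2), time_h = times_std,
                   rfu = control)
  ))))
  map <- as_quic_plate_map(tibble::tibble(
    well = paste0("W", seq_len(n_neg + 2)),
    subject = c(paste0("P", rep(1:(n_neg / 2), each = 2)), "CTRL", "CTRL"),
    sample = c(paste0("S", rep(1:(n_neg / 2), each = 2)), "CTRL", "CTRL"),
    specimen = "NS_AN", diagnosis = "PD",
    replicate = c(rep(1:2, n_neg / 2), 1, 2)
  ))
  norm <- normalize_traces(tr, map, calling_config())
  got <- noise_threshold(norm)

  # the noise window pools ALL samples, including the control whose
  # in-window signal is ~0: the analytic moments are those of the mixture
  # of 3 * n_neg offset-noise readings and 3 * 2 zero readings
  n_in <- sum(times_std >= 15 & times_std <= 17)
  w <- n_in * n_neg / (n_in * (n_neg + 2))
  mix_mean <- w * 100
  mix_sd <- sqrt(w * (100^2 + sigma^2) - mix_mean^2)
  analytic <- 100 / 9200 * (mix_mean + 3 * mix_sd)
  # estimator spread from a direct Monte-Carlo of the generator moments
  est <- replicate(500, {
    v <- c(rnorm(n_in * n_neg, 100, sigma), rep(0, n_in * 2))
    100 / 9200 * (mean(v) + 3 * sd(v))
  })
  expect_lt(abs(got - analytic), 3 * sd(est) + abs(mean(est) - analytic))
})

test_that("replicate and sample calls follow the crossing and 2-of-4 rules", {
  times <- seq(0, 90, by = 0.75)
  mk_sig <- function(lag) {
    sigmoid_rfu(times, 800, 8000, t50 = lag + log(8000 / 2000 - 1) / 0.8)
  }
  tr <- make_traces(
    W1 = list(time_h = times, rfu = mk_sig(40.5)),
    W2 = list(time_h = times, rfu = mk_sig(42)),
    W3 = list(time_h = times, rfu = rep(800, length(times))),
    W4 = list(time_h = times, rfu = rep(800, length(times))),
    W5 = list(time_h = times, rfu = mk_sig(81)),   # crosses after cutoff
    W6 = list(time_h = times, rfu = rep(800, length(times))),
    W7 = list(time_h = times, rfu = rep(800, length(times))),
    W8 = list(time_h = times, rfu = rep(800, length(times)))
  )
  map <- make_map(2, n_reps = 4)
  cfg <- calling_config(threshold_mode = "percent_only")
  norm <- normalize_traces(tr, map, cfg)
  calls <- call_samples(norm, cfg)
  reps <- attr(calls, "replicates")

  # 2 of 4 crossed -> positive, with first-reading (no interpolation) lags
  s1 <- calls[calls$sample == "S1", ]
  expect_equal(s1$call, "positive")
  expect_equal(s1$n_positive_replicates, 2L)
  w1 <- reps[reps$well == "W1", ]
  expect_true(w1$crossed)
  expect_equal(w1$lag_time_h %% 0.75, 0)      # lag sits on the reading grid
  expect_equal(w1$lag_time_h, 40.5, tolerance = 0.76)

  # replicate crossing only after the 80-h cutoff does not count
  s2 <- calls[calls$sample == "S2", ]
  expect_equal(s2$call, "negative")
  expect_false(reps$crossed[reps$well == "W5"])
  expect_equal(s2$n_positive_replicates, 0L)
  # endpoint is the mean of final readings at or before cutoff
  last_t <- max(times[times <= 80])
  endpoint <- mean(norm$data$percent[norm$data$sample == "S2" &
                                       norm$data$time_h == last_t])
  expect_equal(s2$endpoint_mean_percent, endpoint)
})

test_that("fewer than two replicates is an error; 2-3 replicates are flagged", {
  times <- seq(0, 90, by = 0.75)
  tr3 <- make_traces(
    W1 = list(time_h = times, rfu = sigmoid_rfu(times, 800, 8000, 45)),
    W2 = list(time_h = times, rfu = sigmoid_rfu(times, 800, 8000, 46)),
    W3 = list(time_h = times, rfu = rep(800, length(times)))
  )
  map3 <- make_map(1, n_reps = 3)
  cfg <- calling_config(threshold_mode = "percent_only")
  calls3 <- call_samples(normalize_traces(tr3, map3, cfg), cfg)
  expect_equal(calls3$call, "positive")
  expect_true(calls3$underreplicated)

  tr1 <- make_traces(W1 = list(time_h = times,
                               rfu = sigmoid_rfu(times, 800, 8000, 45)))
  map1 <- make_map(1, n_reps = 1)
  expect_error(call_samples(normalize_traces(tr1, map1, cfg), cfg),
               "insufficient", class = "rtquic_validation_error")
})

test_that("group kinetic summaries average positive samples only", {
  run <- random_run(n_samples = 6, seed = 55)
  rep <- run_calling(run$traces, run$map)
  calls <- rep$calls
  res <- summarize_group_kinetics(calls, rep$normalized, calls$sample)
  pos <- calls[calls$call == "positive", ]
  if (nrow(pos) > 0) {
    expect_equal(res$mean_endpoint_percent, mean(pos$endpoint_mean_percent))
    expect_equal(res$mean_lag_h, mean(unlist(pos$lag_times)))
  }
  expect_equal(res$n_samples, nrow(calls))
  expect_error(summarize_group_kinetics(calls, rep$normalized, "NOPE"),
               class = "rtquic_validation_error")

  # two crossing replicates with lags 40 and 44 -> mean lag 42
  times <- seq(0, 90, by = 0.75)
  mk <- function(lag) sigmoid_rfu(times, 800, 8000,
                                  lag + log(8000 / 2000 - 1) / 0.8)
  tr <- make_traces(
    W1 = list(time_h = times, rfu = mk(40 - 0.2)),
    W2 = list(time_h = times, rfu = mk(44 - 0.2))
  )
  cfg <- calling_config(threshold_mode = "percent_only")
  norm <- normalize_traces(tr, make_map(1, n_reps = 2), cfg)
  calls2 <- call_samples(norm, cfg)
  res2 <- summarize_group_kinetics(calls2, norm, "S1")
  expect_equal(res2$mean_lag_h, 42, tolerance = 0.02)
})

test_that("normalizing an already sample-normalized noiseless set is idempotent", {
  times <- seq(0, 90, by = 0.75)
  tr <- make_traces(
    W1 = list(time_h = times, rfu = sigmoid_rfu(times, 800, 9000, 45)),
    W2 = list(time_h = times, rfu = sigmoid_rfu(times, 800, 7000, 50)),
    W3 = list(time_h = times, rfu = sigmoid_rfu(times, 600, 5000, 40)),
    W4 = list(time_h = times, rfu = sigmoid_rfu(times, 600, 4000, 55))
  )
  map <- make_map(2, n_reps = 2)
  cfg <- calling_config(normalization_scope = "sample")
  once <- normalize_traces(tr, map, cfg)
  renorm_input <- as_quic_traces(tibble::tibble(
    well = once$data$well, time_h = once$data$time_h,
    rfu = once$data$percent
  ))
  twice <- normalize_traces(renorm_input, map, cfg)
  expect_equal(twice$data$percent, once$data$percent, tolerance = 1e-9)
})

test_that("calls and lags are invariant to rescaling all raw fluorescence", {
  run <- random_run(n_samples = 4, seed = 77)
  cfg <- calling_config()  # max_of_both: noise threshold in play too
  rep1 <- run_calling(run$traces, run$map, cfg)
  for (scale in c(0.01, 3.7)) {
    scaled <- run$traces
    scaled$rfu <- scaled$rfu * scale
    rep2 <- run_calling(as_quic_traces(scaled), run$map, cfg)
    expect_equal(rep2$calls$call, rep1$calls$call)
    expect_equal(unlist(rep2$calls$lag_times), unlist(rep1$calls$lag_times))
    expect_equal(rep2$normalized$data$percent, rep1$normalized$data$percent)
    expect_equal(attr(rep2$calls, "threshold"), attr(rep1$calls, "threshold"))
  }
})
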