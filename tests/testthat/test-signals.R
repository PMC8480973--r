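test_that("EVS hits its target RMS exactly and respects the band limit", {
  cfg <- evs_config(20, fs = 2000, target_rms_ma = 1.38, seed = 3)
  evs <- generate_evs(cfg)
  expect_equal(sqrt(mean(evs^2)), 1.38, tolerance = 1e-9)
  expect_identical(generate_evs(evs_config(10, fs = 500, target_rms_ma = 0,
                                           seed = 1)),
                   numeric(5000))
  # out-of-band leakage < 1% of total power
  pg <- Mod(fft(evs))^2
  f <- (seq_along(evs) - 1) / length(evs) * 2000
  f <- pmin(f, 2000 - f)
  expect_lt(sum(pg[f > 30]) / sum(pg[-1]), 0.01)
  expect_error(generate_evs(evs_config(0.05, fs = 500, seed = 1)), "warm-up")
})

test_that("EVS in-band spectrum is flat within 3 dB after segment averaging", {
  fs <- 500
  evs <- generate_evs(evs_config(80, fs = fs, seed = 8))
  sp <- segment_spectra(evs, evs, nfft = 512, fs = fs)
  half <- seq_len(257)
  inband <- sp$freq[half] > 2 & sp$freq[half] < 22
  P <- sp$Pss[half][inband]
  expect_lt(max(10 * log10(P / mean(P))), 3)
  expect_gt(min(10 * log10(P / mean(P))), -3)
})

test_that("coupling kernel is biphasic with peaks at the stated latencies", {
  k <- coupling_kernel(vestibular_coupling(), fs = 2000)
  lag_ms <- (seq_along(k) - 1) / 2
  expect_lt(abs(lag_ms[which.max(k)] - 60), 5)
  expect_lt(abs(lag_ms[which.min(k)] - 100), 5)
  expect_gt(max(k), 0)
  expect_lt(min(k), 0)
})

test_that("EMG generator honours degenerate inputs", {
  fs <- 500
  tr <- trial_record(time_s = (0:(10 * fs - 1)) / fs, fs = fs)
  evs <- generate_evs(evs_config(10, fs = fs, seed = 2))
  # all-off: zero tonic, zero inputs -> all-zero envelope
  off <- vestibular_coupling(gain_schedule = function(t) rep(0, length(t)))
  expect_identical(generate_emg(tr, numeric(10 * fs), off, tonic = 0,
                                noise_std = 0),
                   rep(0, 10 * fs))
  expect_error(generate_emg(tr, evs[1:100], off), "mismatch")
})

test_that("decoupled EMG shows only chance-level coherence", {
  fs <- 2000
  tr <- trial_record(time_s = (0:(40 * fs - 1)) / fs, fs = fs)
  evs <- generate_evs(evs_config(40, fs = fs, seed = 4))
  off <- vestibular_coupling(gain_schedule = function(t) rep(0, length(t)))
  emg <- generate_emg(tr, evs, off, tonic = 10, noise_std = 1, seed = 5)
  co <- coherence(segment_spectra(evs, emg, 2048, fs))
  expect_gt(mean(!co$significant[-1]), 0.90)
})

test_that("unit coupling reproduces the injected kernel via cross-covariance", {
  fs <- 2000
  tr <- trial_record(time_s = (0:(40 * fs - 1)) / fs, fs = fs)
  evs <- generate_evs(evs_config(40, fs = fs, seed = 6))
  cp <- vestibular_coupling(amplitude = 0.2)
  emg <- generate_emg(tr, evs, cp, tonic = 10, noise_std = 0)
  q <- cross_covariance(segment_spectra(evs, emg, 2048, fs))
  pp <- peak_to_peak(q)
  expect_false(pp$absent)
  expect_lt(abs(pp$short$lag_s - 0.060), 0.005)
  expect_lt(abs(pp$medium$lag_s - 0.100), 0.005)
  expect_gt(pp$short$value, 0)
  expect_lt(pp$medium$value, 0)
})

test_that("button generation follows the psychometric truth", {
  fs <- 100
  truth <- percept_truth(mu_s = 0.15, sigma_s = 0.05, delta = 0,
                         false_press_rate_per_min = 0)
  # far above mu: always detected
  periods <- data.frame(onset_s = seq(5, by = 16, length.out = 10),
                        delay_ms = 650, duration_s = 8)   # mu + 10 sigma
  btn <- generate_button(periods, 170, truth, fs = fs, seed = 1)
  out <- classify_periods(btn, fs, periods)
  expect_true(all(out$status == "detected"))
  # at mu: detection probability 1/2 regardless of lapse
  truth2 <- percept_truth(mu_s = 0.15, sigma_s = 0.05, delta = 0.04,
                          false_press_rate_per_min = 0)
  periods2 <- data.frame(onset_s = seq(5, by = 16, length.out = 300),
                         delay_ms = 150, duration_s = 8)
  btn2 <- generate_button(periods2, 16 * 300 + 10, truth2, fs = fs, seed = 2)
  rate <- mean(classify_periods(btn2, fs, periods2)$status == "detected")
  expect_lt(abs(rate - 0.5), 1.96 * sqrt(0.25 / 300) + 1e-9)
})

test_that("empirical detection proportions sit inside binomial bands", {
  fs <- 100
  truth <- percept_truth(false_press_rate_per_min = 0)
  levels <- c(50, 100, 150, 200, 250, 300, 350)
  hits <- integer(7); n_per <- 20
  for (i in seq_along(levels)) {
    periods <- data.frame(onset_s = seq(5, by = 16, length.out = n_per),
                          delay_ms = levels[i], duration_s = 8)
    btn <- generate_button(periods, 16 * n_per + 10, truth, fs = fs,
                           seed = 100 + i)
    hits[i] <- sum(classify_periods(btn, fs, periods)$status == "detected")
  }
  p <- mixture_probability(levels / 1000, truth$mu_s, truth$sigma_s,
                           truth$delta)
  band <- 1.96 * sqrt(p * (1 - p) / n_per)
  expect_true(all(abs(hits / n_per - p) <= band + 1e-9))
})

test_that("button state is binary with alternating presses and releases", {
  fs <- 100
  truth <- percept_truth()
  periods <- data.frame(onset_s = seq(5, by = 16, length.out = 12),
                        delay_ms = 250, duration_s = 8)
  btn <- generate_button(periods, 16 * 12 + 10, truth, fs = fs, seed = 3)
  expect_true(all(btn %in% c(0L, 1L)))
  edges <- diff(btn)
  starts <- which(edges == 1L); ends <- which(edges == -1L)
  expect_true(abs(length(starts) - length(ends)) <= 1)
  if (length(starts) && length(ends))
    expect_true(all(ends[seq_len(min(length(starts), length(ends)))] >
                      starts[seq_len(min(length(starts), length(ends)))]))
})

test_that("session designs honour the per-experiment invariants", {
  # exp2-percept: 10 trials -> 14 periods each, 20 per level, ITI in [7, 10]
  d <- make_session("exp2-percept", seed = 4)
  expect_length(d$trials, 10)
  all_periods <- do.call(rbind, lapply(d$trials, `[[`, "periods"))
  expect_true(all(table(all_periods$delay_ms) == 20))
  expect_equal(nrow(all_periods), 140)
  for (tr in d$trials) {
    expect_equal(nrow(tr$periods), 14)
    expect_true(all(tr$periods$duration_s == 8))
    iti <- diff(tr$periods$onset_s) - 8
    expect_true(all(iti >= 7 - 1e-9 & iti <= 10 + 1e-9))
  }
  # exp3: 6 trials x 14 periods, all 200 ms, ITI in [8, 9]
  d3 <- make_session("exp3", seed = 4)
  expect_equal(n_periods(d3), 84)
  expect_true(all(unlist(lapply(d3$trials, function(tr) tr$periods$delay_ms))
                  == 200))
  for (tr in d3$trials) {
    iti <- diff(tr$periods$onset_s) - 8
    expect_true(all(iti >= 8 - 1e-9 & iti <= 9 + 1e-9))
  }
  # exp2-vest: four 20 s trials per delay and condition
  dv <- make_session("exp2-vest", seed = 4)
  expect_length(dv$trials, 24)
  expect_true(all(vapply(dv$trials, `[[`, numeric(1), "duration_s") == 20))
  delays <- vapply(dv$trials, function(tr) tr$periods$delay_ms[1], numeric(1))
  expect_true(all(table(delays) == 4))
  # determinism and error handling
  expect_identical(make_session("exp3", seed = 9), make_session("exp3", seed = 9))
  expect_error(make_session("exp9"), "valid tags")
})

test_that("synthesized experiments are reproducible with a ground-truth sidecar", {
  s1 <- synthesize_experiment("exp1", seed = 6,
                              params = fast_params(100))
  s2 <- synthesize_experiment("exp1", seed = 6,
                              params = fast_params(100))
  expect_identical(lapply(s1$trials, as.data.frame),
                   lapply(s2$trials, as.data.frame))
  expect_length(s1$trials, 6)
  expect_equal(vapply(s1$trials, function(tr) tr$delay_ms[1], numeric(1)),
               c(20, 100, 200, 300, 400, 500))
  expect_true(all(vapply(s1$trials, nrow, numeric(1)) == 60 * 100))
  # sidecar carries the generating parameters
  expect_equal(s1$truth$mu_s, percept_truth()$mu_s)
  expect_equal(s1$truth$evs_rms_ma, 1.38)
})
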