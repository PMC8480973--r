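test_that("window extraction follows the floor rule per in-limit run", {
  fs <- 100
  lim <- fast_limits()
  mk <- function(runs_s) {
    # alternate in-limit (0 deg) and out-of-limit (10 deg) stretches
    unlist(lapply(seq_along(runs_s), function(i)
      rep(if (i %% 2 == 1) 0 else 10, round(runs_s[i] * fs))))
  }
  # an 11 s continuous run yields exactly five 2 s windows
  w <- extract_windows(mk(c(11)), fs, lim)
  expect_equal(nrow(w), 5)
  expect_equal(w$end_s - w$start_s, rep(2, 5))
  # below-threshold run yields none
  expect_equal(nrow(extract_windows(mk(c(1.99)), fs, lim)), 0)
  # 4.0 s and 3.5 s runs -> 2 + 1 windows
  expect_equal(nrow(extract_windows(mk(c(4, 1, 3.5)), fs, lim)), 3)
  # empty trace -> empty set
  expect_equal(nrow(extract_windows(numeric(0), fs, lim)), 0)
})

test_that("windows are disjoint and inside in-limit runs", {
  fs <- 100
  lim <- fast_limits()
  set.seed(21)
  theta <- 8 * fft_butterworth(rnorm(3000), fs, 0.5, 4, "low")
  w <- extract_windows(theta, fs, lim)
  if (nrow(w) > 1) expect_true(all(diff(w$start_s) >= 2 - 1e-9))
  for (i in seq_len(nrow(w))) {
    idx <- (round(w$start_s[i] * fs) + 1):round(w$end_s[i] * fs)
    expect_true(all(theta[idx] <= 6 & theta[idx] >= -3))
  }
  # shifting by whole samples within a run preserves the window count
  w2 <- extract_windows(c(theta[1], theta[-length(theta)]), fs, lim)
  expect_equal(nrow(w2), nrow(w))
})

test_that("sway velocity variance matches closed forms", {
  fs <- 200
  lim <- fast_limits()
  # constant velocity -> zero variance
  tr <- trial_record(time_s = (0:(4 * fs - 1)) / fs,
                     theta_deg = seq(0, 1, length.out = 4 * fs), fs = fs)
  v <- sway_velocity_variance(tr, limits = lim)
  expect_lt(v$mean_variance, 1e-10)
  # sinusoidal velocity A sin(2 pi t), window = 2 whole periods -> A^2/2
  A <- 3
  vel <- A * sin(2 * pi * (0:(2 * fs - 1)) / fs)
  w1 <- data.frame(start_s = 0, end_s = 2)
  tr2 <- trial_record(time_s = (0:(2 * fs - 1)) / fs,
                      theta_dot_dps = vel, fs = fs)
  v2 <- sway_velocity_variance(tr2, windows = w1, limits = lim)
  expect_equal(v2$mean_variance, A^2 / 2 * (2 * fs) / (2 * fs - 1),
               tolerance = 1e-9)
  # averaging across windows is the plain mean of per-window variances
  expect_equal(sway_velocity_variance(tr2,
                 windows = data.frame(start_s = c(0, 1), end_s = c(1, 2)),
                 limits = lim)$mean_variance,
               mean(c(var(vel[1:fs]), var(vel[(fs + 1):(2 * fs)]))))
})

test_that("no windows yields an explicit NA sentinel, never silent zero", {
  fs <- 100
  tr <- trial_record(time_s = (0:(3 * fs - 1)) / fs,
                     theta_deg = rep(10, 3 * fs), fs = fs)
  v <- sway_velocity_variance(tr, limits = fast_limits())
  expect_true(is.na(v$mean_variance))
  expect_identical(v$n_windows, 0L)
})

test_that("percent within limits counts samples per interval", {
  fs <- 100
  lim <- fast_limits()
  expect_equal(percent_within_limits(rep(0, 60 * fs), fs, lim), 100)
  expect_equal(percent_within_limits(rep(10, 60 * fs), fs, lim), 0)
  theta <- c(rep(10, 27 * fs), rep(0, 33 * fs))
  expect_equal(percent_within_limits(theta, fs, lim), 55)
  expect_error(percent_within_limits(rep(0, 10 * fs), fs, lim), "allow_partial")
  expect_length(percent_within_limits(rep(0, 130 * fs), fs, lim), 2)
})

test_that("sliding variance equals the brute-force definition", {
  fs <- 50
  set.seed(31)
  x <- rnorm(400)
  v <- sliding_velocity_variance(x, fs, window_s = 2)
  w <- 2 * fs; half <- w %/% 2
  brute <- vapply(seq_along(x), function(i) {
    idx <- max(i - half, 1):min(i + w - half - 1, length(x))
    var(x[idx])
  }, numeric(1))
  expect_equal(v, brute, tolerance = 1e-12)
  expect_true(all(sliding_velocity_variance(rep(2, 300), fs) == 0))
})

test_that("sliding variance responds before a noise step by at most 1 s", {
  fs <- 100
  set.seed(32)
  x <- c(rnorm(10 * fs, sd = 0.01), rnorm(5 * fs, sd = 5))
  v <- sliding_velocity_variance(x, fs, window_s = 2)
  first_rise <- which(v > 25 * 0.01^2)[1] / fs
  expect_gte(first_rise, 10 - 1)
  expect_lte(first_rise, 10 + 1)
})

test_that("peak variance before detection picks the interval maximum", {
  fs <- 100
  v <- rep(1, 20 * fs)
  v[12 * fs + seq_len(fs)] <- 9        # bump inside [onset, press]
  expect_equal(peak_variance_before_detection(v, fs, 10, 15), 9)
  # monotone rising variance -> value at the press
  vr <- seq_len(20 * fs) / fs
  expect_equal(peak_variance_before_detection(vr, fs, 10, 15), vr[15 * fs + 1])
  # degenerate one-sample interval
  expect_equal(peak_variance_before_detection(vr, fs, 10, 10 + 1 / fs),
               max(vr[10 * fs + 1:2]))
  expect_error(peak_variance_before_detection(v, fs, 10, 10), "excluded")
})

test_that("exponential fit recovers noiseless parameters to 1e-6", {
  x <- seq(1, 100, by = 1)
  y <- 11.61 * exp(-x / 27.86) + 2.17
  fit <- fit_exponential(x, y)
  expect_equal(fit$a, 11.61, tolerance = 1e-6)
  expect_equal(fit$b, 27.86, tolerance = 1e-6)
  expect_equal(fit$c, 2.17, tolerance = 1e-6)
  y2 <- -37.38 * exp(-x / 32.45) + 99.12
  fit2 <- fit_exponential(x, y2)
  expect_equal(fit2$b, 32.45, tolerance = 1e-5)
  expect_true(fit2$identifiable)
})

test_that("landmark identities hold to 1e-12 for every returned fit", {
  set.seed(41)
  for (rep in 1:10) {
    x <- sort(runif(30, 0, 50))
    y <- runif(1, 1, 20) * exp(-x / runif(1, 2, 20)) + runif(1, -5, 5) +
      rnorm(30, sd = 0.1)
    fit <- fit_exponential(x, y)
    f <- function(t) fit$a * exp(-t / fit$b) + fit$c
    expect_equal(f(fit$b) - fit$c, fit$a * exp(-1), tolerance = 1e-12)
    expect_equal(f(3 * fit$b) - fit$c, fit$a * exp(-3), tolerance = 1e-12)
    expect_equal(fit$value_at_tc, f(fit$b), tolerance = 1e-12)
    expect_identical(fit$t95, 3 * fit$t63)
  }
})

test_that("constant data is flagged unidentifiable", {
  fit <- fit_exponential(1:10, rep(5, 10))
  expect_false(fit$identifiable)
  expect_equal(fit$c + fit$a * mean(exp(-(1:10) / fit$b)), 5, tolerance = 1e-6)
})

test_that("attenuation landmarks follow the definition", {
  fit <- fit_exponential(seq(0, 10, by = 0.25), 4 * exp(-seq(0, 10, by = 0.25) / 2) + 1)
  expect_equal(attenuation_at(fit, fit$b), 100 * (1 - exp(-1)), tolerance = 1e-6)
  expect_equal(attenuation_at(fit, 3 * fit$b), 100 * (1 - exp(-3)), tolerance = 1e-6)
  expect_equal(attenuation_at(fit, 0), 0)
})
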