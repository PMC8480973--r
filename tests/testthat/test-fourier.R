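test_that("EMG preprocessing kills DC, rectifies, and adds no phase lag", {
  fs <- 2000
  t <- (0:(4 * fs - 1)) / fs
  # DC input -> ~0 after the high-pass
  out <- preprocess_emg(rep(5, length(t)), fs)
  expect_lt(max(out[(fs):(3 * fs)]), 1e-6)
  # 50 Hz sinusoid: rectified mean = 2A/pi (passband, gain ~1)
  A <- 2
  out50 <- preprocess_emg(A * sin(2 * pi * 50 * t), fs)
  # passband gain of the order-6 cascade at 50 Hz is (1+(30/50)^6)^-1 = 0.955
  expect_equal(mean(out50[fs:(3 * fs)]), 2 * A / pi / (1 + (30 / 50)^6),
               tolerance = 0.01)
  # zero phase: the filtered (pre-rectification) 50 Hz carrier aligns with
  # the input at zero cross-correlation lag
  y <- fft_butterworth(sin(2 * pi * 50 * t), fs, 30, 6, "high")
  cc <- ccf(y[fs:(3 * fs)], sin(2 * pi * 50 * t)[fs:(3 * fs)],
            lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(preprocess_emg(rnorm(100), fs = 50), "high-pass")
})

test_that("EMG scaling divides by the in-band quiet-standing mean", {
  set.seed(51)
  quiet_theta <- rnorm(1000, sd = 0.2)
  quiet_emg <- rep(2, 1000)
  scaled <- scale_emg(rep(2, 50), quiet_theta, quiet_emg)
  expect_equal(as.numeric(scaled), rep(1, 50))
  expect_equal(as.numeric(scale_emg(5, quiet_theta, quiet_emg)), 2.5)
  # the band enters only through the masked mean
  quiet_emg2 <- ifelse(abs(quiet_theta - median(quiet_theta)) <= 0.1, 4, 100)
  s2 <- scale_emg(8, quiet_theta, quiet_emg2, band_deg = 0.1)
  expect_equal(as.numeric(s2), 2)
  expect_equal(attr(s2, "baseline"),
               mean(quiet_emg2[abs(quiet_theta - median(quiet_theta)) <= 0.1]))
  expect_error(scale_emg(1, c(0, 10), c(1, 1), band_deg = 1e-12),
               "quiet-standing")
})

test_that("segment bookkeeping matches the stated resolution and counts", {
  sp <- segment_spectra(rnorm(80 * 2000), rnorm(80 * 2000), 2048, 2000)
  expect_equal(sp$freq[2], 2000 / 2048)
  expect_equal(sp$L, 78)
  # 76 segments span 76 * 2048 samples = 77.82 s at 2000 Hz
  n76 <- 76 * 2048
  expect_equal(round(n76 / 2000, 2), 77.82)
  expect_equal(segment_spectra(rnorm(n76), rnorm(n76), 2048, 2000)$L, 76)
  expect_error(segment_spectra(rnorm(100), rnorm(100), 2048, 2000), "segment")
  expect_error(segment_spectra(rnorm(5000), rnorm(4000), 2048, 2000),
               "mismatch")
})

test_that("self-coherence is 1 and the Cauchy-Schwarz bound always holds", {
  set.seed(52)
  x <- rnorm(8 * 256)
  co <- coherence(segment_spectra(x, x, 256, 1000))
  expect_true(all(abs(co$coherence[!co$undefined] - 1) < 1e-10))
  for (rep in 1:5) {
    a <- rnorm(6 * 128); b <- 0.3 * a + rnorm(6 * 128)
    cab <- coherence(segment_spectra(a, b, 128, 500))
    expect_true(all(cab$coherence[!cab$undefined] <= 1 + 1e-10))
    expect_true(all(cab$coherence[!cab$undefined] >= -1e-10))
  }
})

test_that("coherence, gain and cross-covariance match the brute-force oracle", {
  set.seed(53)
  pair <- coupled_pair(10 * 128, gain = 2, noise_sd = 1)
  sp <- segment_spectra(pair$x, pair$y, 128, 500)
  ref <- brute_spectra(pair$x, pair$y, 128, 500)
  expect_equal(sp$L, ref$L)
  expect_lt(max(abs(sp$Pss - ref$Pss)), 1e-10)
  expect_lt(max(abs(sp$Prr - ref$Prr)), 1e-10)
  expect_lt(max(Mod(sp$Psr - ref$Psr)), 1e-10)
  co <- coherence(sp)
  C_ref <- (Mod(ref$Psr)^2 / (ref$Pss * ref$Prr))[1:65]
  expect_lt(max(abs(co$coherence - C_ref), na.rm = TRUE), 1e-10)
  g <- gain(sp)
  expect_lt(max(abs(g$gain - (Mod(ref$Psr) / ref$Pss)[1:65]), na.rm = TRUE),
            1e-10)
  q <- cross_covariance(sp)
  q_ref <- Re(fft(ref$Psr, inverse = TRUE)) / 128
  expect_lt(max(abs(sort(q$q) - sort(q_ref))), 1e-10)
})

test_that("the 95% coherence limit matches its closed form and calibrates", {
  expect_equal(coherence_limit(76), 1 - 0.05^(1 / 75))
  expect_lt(abs(coherence_limit(76) - 0.0392), 5e-4)
  expect_error(coherence_limit(1), "2 segments")
  # limit decreases monotonically with more segments
  expect_true(all(diff(vapply(2:50, coherence_limit, numeric(1))) < 0))
  # false-positive rate for independent noise (a light version; the full
  # 200-pair calibration lives in the acceptance suite)
  set.seed(54)
  fp <- replicate(30, {
    co <- coherence(segment_spectra(rnorm(76 * 128), rnorm(76 * 128),
                                    128, 500))
    mean(co$significant[2:64])
  })
  expect_gt(mean(fp), 0.03)
  expect_lt(mean(fp), 0.07)
})

test_that("gain recovers scalar and filtered systems where coherent", {
  set.seed(55)
  pair <- coupled_pair(20 * 256, gain = 3, noise_sd = 0)
  g <- gain(segment_spectra(pair$x, pair$y, 256, 1000))
  expect_true(all(abs(g$gain[!is.na(g$gain)] - 3) < 1e-8))
  # known FIR filter: |H(f)| recovered at coherent frequencies
  h <- c(0.4, 0.3, 0.2, 0.1)
  x <- rnorm(40 * 256)
  y <- as.numeric(stats::filter(x, h, sides = 1)); y[is.na(y)] <- 0
  y <- y + rnorm(length(y), sd = 0.05)
  sp <- segment_spectra(x, y, 256, 1000)
  g2 <- gain(sp)
  H <- Mod(fft(c(h, numeric(252))))[1:129]
  ok <- g2$reliable & H > 0.2
  expect_lt(median(abs(g2$gain[ok] - H[ok]) / H[ok]), 0.1)
  # independent signals: ~95% flagged unreliable
  go <- gain(segment_spectra(rnorm(76 * 128), rnorm(76 * 128), 128, 500))
  expect_gt(mean(!go$reliable), 0.85)
})

test_that("cross-covariance localizes a pure delay and calibrates its CI", {
  set.seed(56)
  n <- 20 * 256
  x <- rnorm(n)
  y <- c(numeric(10), x[1:(n - 10)])        # response lags stimulus by 10
  q <- cross_covariance(segment_spectra(x, y, 256, 1000))
  expect_equal(q$lag_s[which.max(q$q)], 10 / 1000)
  # under independence about 5% of lags breach the 95% interval
  frac <- replicate(20, {
    sp0 <- segment_spectra(rnorm(76 * 128), rnorm(76 * 128), 128, 500)
    q0 <- cross_covariance(sp0)
    mean(abs(q0$q) > attr(q0, "ci95"))
  })
  expect_lt(abs(mean(frac) - 0.05), 0.02)
  # the phase-randomization bootstrap agrees with the analytic width
  sp0 <- segment_spectra(rnorm(76 * 128), rnorm(76 * 128), 128, 500)
  q0 <- cross_covariance(sp0)
  bs <- cross_covariance_bootstrap(sp0, n_boot = 400, seed = 2)
  expect_lt(abs(bs - attr(q0, "ci95")) / attr(q0, "ci95"), 0.35)
})

test_that("peak-to-peak zeroes sub-threshold lobes and flags absence", {
  lag_s <- seq(-0.2, 0.2, by = 0.001)
  mk <- function(short, medium) {
    q <- data.frame(lag_s = lag_s, q = 0)
    q$q[which.min(abs(lag_s - 0.060))] <- short
    q$q[which.min(abs(lag_s - 0.110))] <- medium
    q
  }
  # both above threshold: |short - medium|
  pp <- peak_to_peak(mk(5, -4), ci95 = 1)
  expect_equal(pp$peak_to_peak, 9)
  expect_false(pp$absent)
  # only short significant: medium zeroed
  pp2 <- peak_to_peak(mk(5, -0.5), ci95 = 1)
  expect_equal(pp2$peak_to_peak, 5)
  expect_true(pp2$medium$zeroed)
  # both sub-threshold: amplitude 0, response absent
  pp3 <- peak_to_peak(mk(0.5, -0.5), ci95 = 1)
  expect_equal(pp3$peak_to_peak, 0)
  expect_true(pp3$absent)
})

test_that("pooling averages spectra across all segments", {
  set.seed(57)
  mk <- function(n_seg, seed) {
    set.seed(seed)
    pair <- coupled_pair(n_seg * 128, gain = 2, noise_sd = 1, seed = seed)
    segment_spectra(pair$x, pair$y, 128, 500)
  }
  a <- mk(6, 1); b <- mk(6, 2)
  pooled <- pool_participants(list(a, b))
  expect_equal(pooled$L, 12)
  expect_equal(pooled$Pss, (a$Pss + b$Pss) / 2)
  expect_equal(pooled$Psr, (a$Psr + b$Psr) / 2)
  # single participant: identity
  expect_equal(pool_participants(list(a)), a)
  # pooling lowers the coherence limit
  expect_lt(coherence_limit(pooled$L), coherence_limit(a$L))
  expect_error(pool_participants(list(a, segment_spectra(rnorm(512),
                                                         rnorm(512),
                                                         256, 500))),
               "mismatch")
})
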