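#' Complex Morlet wavelet bank
#'
#' Forty complex Morlet wavelets (complex sine tapered by a Gaussian) with
#' peak frequencies linearly spaced over 0.5-25 Hz and cycle counts
#' geometrically ("logarithmically") spaced from 3 to 12 with increasing
#' frequency. Temporal FWHM of the Gaussian envelope is
#' 2 sqrt(2 ln 2) n / (2 pi f); spectral FWHM is 2 sqrt(2 ln 2) f / n.
#' Under these spacing rules the temporal FWHM spans 168-2249 ms and the
#' spectral FWHM 0.39-5.25 Hz across the bank (the temporal minimum falls at
#' an interior wavelet, not the highest frequency).
#'
#' @param n_wavelets number of wavelets.
#' @param freq_range peak frequency range (Hz).
#' @param cycle_range cycle-count range, spaced geometrically.
#' @return object of class `wavelet_bank`: data.frame with `freq_hz`,
#'   `cycles`, `sigma_t_s`, `fwhm_t_s`, `fwhm_f_hz`.
#' @export
morlet_bank <- function(n_wavelets = 40, freq_range = c(0.5, 25),
                        cycle_range = c(3, 12)) {
  f <- seq(freq_range[1], freq_range[2], length.out = n_wavelets)
  n <- cycle_range[1] *
    (cycle_range[2] / cycle_range[1])^((seq_len(n_wavelets) - 1) / (n_wavelets - 1))
  sigma_t <- n / (2 * pi * f)
  k <- 2 * sqrt(2 * log(2))
  out <- data.frame(freq_hz = f, cycles = n, sigma_t_s = sigma_t,
                    fwhm_t_s = k * sigma_t, fwhm_f_hz = k * f / n)
  class(out) <- c("wavelet_bank", "data.frame")
  out
}

# sample one zero-mean, unit-energy complex Morlet wavelet at rate fs
sample_morlet <- function(freq_hz, sigma_t_s, fs) {
  half <- ceiling(5 * sigma_t_s * fs)
  t <- (-half:half) / fs
  g <- exp(-t^2 / (2 * sigma_t_s^2))
  # kappa correction removes the DC of the tapered sinusoid; the residual
  # discrete-sampling mean is subtracted exactly
  kappa <- exp(-(2 * pi * freq_hz * sigma_t_s)^2 / 2)
  w <- (exp(2i * pi * freq_hz * t) - kappa) * g
  w <- w - mean(w)
  w / sqrt(sum(Mod(w)^2))
}

# centered complex convolution with reflection padding, via FFT
conv_center <- function(x, w) {
  n <- length(x); m <- length(w); half <- (m - 1L) %/% 2L
  pad <- min(n - 1L, m)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  np <- length(xp) + m - 1L
  X <- fft(c(xp, complex(real = numeric(m - 1L))))
  W <- fft(c(w, complex(real = numeric(length(xp) - 1L))))
  y <- fft(X * W, inverse = TRUE) / np
  y[pad + half + seq_len(n)]
}

#' Time-frequency stimulus-EMG coupling around delay transitions
#'
#' Convolves stimulus and EMG with every wavelet in the bank, averages the
#' per-transition cross and auto products across transitions, and forms
#' coherence and gain on the (time x frequency) grid. Segments should span
#' 24 s: 8 s before onset, the 8 s delay period, 8 s after. The first and
#' last `trim_s` are removed (wavelet edge distortion); the significance
#' limit is 1 - alpha^(1/(K-1)) with K the transition count (a 99% limit by
#' default, the stricter of the two limits in use).
#'
#' @param segments list of transitions; each element a list with `evs` and
#'   `emg` vectors of equal common length.
#' @param fs sample rate (Hz).
#' @param bank `wavelet_bank`.
#' @param onset_s time of delay onset within each segment (s).
#' @param trim_s seconds trimmed from each end of the map.
#' @param alpha significance level for the coherence limit.
#' @return object of class `tf_map`: `time_s` (relative to onset),
#'   `freq_hz`, matrices `coherence` and `gain` (freq x time), `mask`
#'   (significant coherence), `K`, `limit`.
#' @export
tf_coupling <- function(segments, fs, bank = morlet_bank(), onset_s = 8,
                        trim_s = 2, alpha = 0.01) {
  K <- length(segments)
  if (K < 2L) stopf("need at least 2 transitions (coherence undefined)")
  n <- length(segments[[1]]$evs)
  for (sg in segments)
    if (length(sg$evs) != n || length(sg$emg) != n)
      stopf("all transition segments must share one length")
  nf <- nrow(bank)
  keep <- seq.int(as.integer(trim_s * fs) + 1L, n - as.integer(trim_s * fs))
  wavelets <- lapply(seq_len(nf), function(i)
    sample_morlet(bank$freq_hz[i], bank$sigma_t_s[i], fs))
  m_max <- max(lengths(wavelets))
  pad <- min(n - 1L, (m_max - 1L) %/% 2L)   # covers every wavelet half-width
  # 2-3-5-smooth FFT length: R's mixed-radix FFT degrades badly on sizes
  # with large prime factors
  NF <- stats::nextn(n + 2L * pad + m_max - 1L, c(2L, 3L, 5L))
  # batch all segments: one forward FFT per channel, reused for every wavelet
  pad_mat <- function(field) {
    vapply(segments, function(sg) {
      x <- sg[[field]] - mean(sg[[field]])
      c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]),
        numeric(NF - n - 2L * pad))
    }, numeric(NF))
  }
  Xs <- stats::mvfft(pad_mat("evs"))
  Xr <- stats::mvfft(pad_mat("emg"))
  Cmat <- Gmat <- matrix(NA_real_, nf, length(keep))
  for (i in seq_len(nf)) {
    w <- wavelets[[i]]
    half <- (length(w) - 1L) %/% 2L
    W <- fft(c(w, complex(real = numeric(NF - length(w)))))
    Ys <- stats::mvfft(Xs * W, inverse = TRUE)[pad + half + keep, , drop = FALSE] / NF
    Yr <- stats::mvfft(Xr * W, inverse = TRUE)[pad + half + keep, , drop = FALSE] / NF
    cross <- rowSums(Conj(Ys) * Yr)
    auto_s <- rowSums(Mod(Ys)^2)
    auto_r <- rowSums(Mod(Yr)^2)
    Cmat[i, ] <- Mod(cross)^2 / (auto_s * auto_r)
    Gmat[i, ] <- Mod(cross) / auto_s
  }
  lim <- coherence_limit(K, alpha)
  structure(list(time_s = (keep - 1) / fs - onset_s,
                 freq_hz = bank$freq_hz,
                 coherence = Cmat, gain = Gmat,
                 mask = Cmat > lim, K = K, limit = lim, trim_s = trim_s,
                 alpha = alpha),
            class = "tf_map")
}

#' Band-mean coherence and gain time series
#'
#' Coherence is averaged over the full band at each time point. Gain is
#' averaged only over cells with significant coherence; time points with no
#' significant cell are flagged gaps (NA gain).
#'
#' @param map `tf_map`.
#' @param band frequency band (Hz) to average over.
#' @return data.frame with `time_s`, `mean_coherence`, `mean_gain`,
#'   `gain_gap`.
#' @export
band_mean <- function(map, band = c(0.5, 25)) {
  rows <- map$freq_hz >= band[1] & map$freq_hz <= band[2]
  co <- colMeans(map$coherence[rows, , drop = FALSE])
  g <- map$gain[rows, , drop = FALSE]
  m <- map$mask[rows, , drop = FALSE]
  gm <- vapply(seq_len(ncol(g)), function(j) {
    sel <- m[, j]
    if (!any(sel)) NA_real_ else mean(g[sel, j])
  }, numeric(1))
  data.frame(time_s = map$time_s, mean_coherence = co, mean_gain = gm,
             gain_gap = is.na(gm))
}

#' Fit the exponential attenuation of band-mean coupling over a delay period
#'
#' Fits f(t) = a exp(-t/b) + c on the delay period and reports the 63.2%
#' attenuation landmark (the time constant b) and the 95% landmark (3 b).
#' A non-decaying series (a <= 0) is returned flagged, not hidden.
#'
#' @param time_s time axis (s, 0 = delay onset).
#' @param series band-mean coherence (or gain) series.
#' @param period delay period (s) to fit over.
#' @return `exp_fit` with additional field `decaying` (a > 0).
#' @export
fit_attenuation <- function(time_s, series, period = c(0, 8)) {
  sel <- time_s >= period[1] & time_s <= period[2] & !is.na(series)
  if (sum(sel) < 4L) stopf("delay period not covered by the series")
  fit <- fit_exponential(time_s[sel], series[sel])
  fit$decaying <- fit$identifiable && fit$a > 0
  fit
}
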