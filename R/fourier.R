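#' Preprocess raw EMG: zero-phase high-pass and full-wave rectification
#'
#' High-pass at 30 Hz with zero phase lag and overall attenuation order 6
#' (the forward-backward reading of "sixth-order, zero lag"; set
#' `order6_twice = TRUE` for the stricter order-6-applied-twice variant),
#' then absolute value.
#'
#' @param x raw EMG series.
#' @param fs sample rate (Hz); must exceed 60 Hz.
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param order6_twice config switch for the overall order (see above).
#' @return rectified envelope series.
#' @export
preprocess_emg <- function(x, fs, cutoff_hz = 30, order6_twice = FALSE) {
  if (fs <= 2 * cutoff_hz)
    stopf("cannot design a %g Hz high-pass at fs = %g Hz", cutoff_hz, fs)
  y <- fft_butterworth(x, fs, cutoff_hz, order = if (order6_twice) 12 else 6,
                       type = "high")
  abs(y)
}

#' Scale an EMG envelope to its quiet-standing baseline
#'
#' The baseline is the mean envelope from a quiet-standing trial, computed
#' only over samples where the body was within +/- `band_deg` of its
#' preferred (median) posture. The scaled envelope is in fractions of
#' baseline EMG (multiply by 100 for %EMG).
#'
#' @param envelope EMG envelope to scale.
#' @param quiet_theta_deg angle series of the quiet-standing trial (deg).
#' @param quiet_emg envelope of the quiet-standing trial.
#' @param band_deg posture band half-width (deg).
#' @return scaled envelope; attribute `baseline` holds the divisor.
#' @export
scale_emg <- function(envelope, quiet_theta_deg, quiet_emg, band_deg = 0.25) {
  pref <- stats::median(quiet_theta_deg)
  inband <- abs(quiet_theta_deg - pref) <= band_deg
  if (!any(inband))
    stopf("no quiet-standing samples within +/-%g deg of the preferred posture",
          band_deg)
  baseline <- mean(quiet_emg[inband])
  if (baseline <= 0) stopf("non-positive baseline EMG")
  out <- envelope / baseline
  attr(out, "baseline") <- baseline
  out
}

#' Segment-averaged auto- and cross-spectra
#'
#' Cuts the aligned stimulus and response into disjoint non-overlapping
#' segments of `nfft` samples (trailing partial segment discarded; the
#' per-channel mean is removed first), Fourier transforms each segment with a
#' rectangular window, and averages the periodograms across the L segments.
#' Frequency resolution is fs/nfft (~0.98 Hz at the default 2048 samples at
#' 2000 Hz).
#'
#' @param evs stimulus series (mA).
#' @param emg response envelope series.
#' @param nfft segment length (samples).
#' @param fs sample rate (Hz).
#' @return object of class `spectra_set`: full-length `freq`, `Pss`, `Prr`
#'   (real), `Psr` (complex), `L`, `nfft`, `fs`.
#' @export
segment_spectra <- function(evs, emg, nfft = 2048, fs = 2000) {
  n <- min(length(evs), length(emg))
  if (length(evs) != length(emg))
    stopf("length mismatch: evs %d vs emg %d samples", length(evs), length(emg))
  L <- n %/% nfft
  if (L == 0L) stopf("series shorter than one segment (nfft = %d)", nfft)
  s <- evs - mean(evs)
  r <- emg - mean(emg)
  Pss <- Prr <- numeric(nfft)
  Psr <- complex(nfft)
  for (k in seq_len(L)) {
    idx <- ((k - 1L) * nfft + 1L):(k * nfft)
    S <- fft(s[idx]); R <- fft(r[idx])
    Pss <- Pss + Mod(S)^2
    Prr <- Prr + Mod(R)^2
    Psr <- Psr + Conj(S) * R
  }
  sc <- 1 / (L * nfft)
  structure(list(freq = (seq_len(nfft) - 1) * fs / nfft,
                 Pss = Pss * sc, Prr = Prr * sc, Psr = Psr * sc,
                 L = L, nfft = nfft, fs = fs),
            class = "spectra_set")
}

#' 95% (or other) coherence confidence limit from L disjoint segments
#'
#' @param L disjoint segment count.
#' @param alpha significance level (default 0.05).
#' @return the limit 1 - alpha^(1/(L-1)).
#' @export
coherence_limit <- function(L, alpha = 0.05) {
  if (L < 2) stopf("need at least 2 segments")
  1 - alpha^(1 / (L - 1))
}

#' Coherence spectrum with confidence limit
#'
#' C(f) = |Psr|^2 / (Pss Prr), in [0, 1]; estimated coupling is deemed
#' significant where C exceeds the limit 1 - 0.05^(1/(L-1)).
#'
#' @param sp `spectra_set`.
#' @param alpha significance level.
#' @return data.frame over 0..Nyquist with columns `freq`, `coherence`,
#'   `significant` and `undefined` (zero autospectrum); attributes `limit`
#'   and `L`.
#' @export
coherence <- function(sp, alpha = 0.05) {
  half <- seq_len(sp$nfft %/% 2 + 1L)
  den <- sp$Pss[half] * sp$Prr[half]
  undef <- den <= 0
  C <- ifelse(undef, NA_real_, Mod(sp$Psr[half])^2 / den)
  lim <- coherence_limit(sp$L, alpha)
  out <- data.frame(freq = sp$freq[half], coherence = C,
                    significant = !is.na(C) & C > lim,
                    undefined = undef)
  attr(out, "limit") <- lim
  attr(out, "L") <- sp$L
  out
}

#' Gain spectrum (|Psr| / Pss) with reliability mask
#'
#' Gain is the modulus of the cross spectrum divided by the stimulus
#' autospectrum (%EMG/mA when the EMG is baseline-scaled). It is unreliable
#' where coherence is below the significance threshold; `reliable` marks the
#' usable frequencies.
#'
#' @param sp `spectra_set`.
#' @param alpha significance level for the underlying coherence mask.
#' @return data.frame with `freq`, `gain`, `reliable`.
#' @export
gain <- function(sp, alpha = 0.05) {
  co <- coherence(sp, alpha)
  half <- seq_len(sp$nfft %/% 2 + 1L)
  g <- ifelse(sp$Pss[half] > 0, Mod(sp$Psr[half]) / sp$Pss[half], NA_real_)
  data.frame(freq = co$freq, gain = g, reliable = co$significant)
}

#' Cross-covariance (cumulant density) from averaged cross-spectra
#'
#' The inverse Fourier transform of the segment-averaged cross spectrum,
#' mapped onto lags (-nfft/2, nfft/2] / fs. Positive lag means the EMG lags
#' the stimulus. The 95% interval is the analytic +/-1.96 SD of the estimator
#' under independence (variance from Pss, Prr, L and nfft); an optional
#' phase-randomization bootstrap cross-check is available via
#' [cross_covariance_bootstrap()].
#'
#' @param sp `spectra_set`.
#' @return data.frame with `lag_s` and `q`; attribute `ci95` (half-width).
#' @export
cross_covariance <- function(sp) {
  n <- sp$nfft
  q <- Re(fft(sp$Psr, inverse = TRUE)) / n
  lag_idx <- c(seq(0, n / 2), seq(-n / 2 + 1, -1))    # FFT bin -> lag samples
  ord <- order(lag_idx)
  ci <- 1.96 * sqrt(sum(sp$Pss * sp$Prr) / sp$L) / n
  out <- data.frame(lag_s = lag_idx[ord] / sp$fs, q = q[ord])
  attr(out, "ci95") <- ci
  out
}

#' @rdname cross_covariance
#' @param n_boot bootstrap replicates (phase randomization of the response
#'   spectrum under the independence null).
#' @param seed RNG seed.
#' @return for the bootstrap: the 95% half-width estimated from the null
#'   distribution of max-free per-lag values.
#' @export
cross_covariance_bootstrap <- function(sp, n_boot = 200, seed = 1) {
  n <- sp$nfft
  vals <- with_seed(seed, {
    sapply(seq_len(n_boot), function(b) {
      ph <- exp(2i * pi * runif(n))
      qb <- Re(fft(sp$Psr * ph, inverse = TRUE)) / n
      qb[sample(n, 1)]
    })
  })
  unname(stats::quantile(abs(vals), 0.95))
}

#' Biphasic peak extraction and peak-to-peak amplitude
#'
#' Finds the extremum of the cross-covariance in the short-latency (50-70 ms)
#' and medium-latency (100-120 ms) windows. A peak that does not exceed the
#' 95% interval is set to zero (recorded, never dropped); the response
#' amplitude is |short - medium| of the possibly-zeroed values, so a response
#' with both peaks sub-threshold has amplitude zero and is considered absent.
#'
#' @param q cross-covariance data.frame from [cross_covariance()].
#' @param ci95 confidence half-width (defaults to the attribute on `q`).
#' @param short_window_s,medium_window_s latency windows (s).
#' @return list: `short`, `medium` (each value, lag_s, zeroed flag),
#'   `peak_to_peak`, `absent`.
#' @export
peak_to_peak <- function(q, ci95 = attr(q, "ci95"),
                         short_window_s = c(0.050, 0.070),
                         medium_window_s = c(0.100, 0.120)) {
  pick <- function(win) {
    idx <- which(q$lag_s >= win[1] & q$lag_s <= win[2])
    v <- q$q[idx]
    i <- idx[which.max(abs(v))]
    val <- q$q[i]
    zeroed <- abs(val) <= ci95
    list(value = if (zeroed) 0 else val, raw = val, lag_s = q$lag_s[i],
         zeroed = zeroed)
  }
  s <- pick(short_window_s); m <- pick(medium_window_s)
  list(short = s, medium = m,
       peak_to_peak = abs(s$value - m$value),
       absent = s$zeroed && m$zeroed)
}

#' Pool spectra across participants
#'
#' Averages spectra over all participants' segments (weighting each
#' participant's averaged spectra by its segment count), as if estimated from
#' the concatenated data; L becomes the total segment count, which lowers the
#' coherence confidence limit monotonically.
#'
#' @param sets list of `spectra_set` with common nfft and fs.
#' @return pooled `spectra_set`.
#' @export
pool_participants <- function(sets) {
  if (!length(sets)) stopf("no spectra to pool")
  nfft <- sets[[1]]$nfft; fs <- sets[[1]]$fs
  for (s in sets)
    if (s$nfft != nfft || s$fs != fs)
      stopf("mismatched nfft/fs across participants")
  Ls <- vapply(sets, `[[`, numeric(1), "L")
  Ltot <- sum(Ls)
  wsum <- function(field)
    Reduce(`+`, Map(function(s, w) s[[field]] * w, sets, Ls)) / Ltot
  structure(list(freq = sets[[1]]$freq,
                 Pss = wsum("Pss"), Prr = wsum("Prr"), Psr = wsum("Psr"),
                 L = Ltot, nfft = nfft, fs = fs),
            class = "spectra_set")
}
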