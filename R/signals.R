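#' Electrical vestibular stimulus (EVS) configuration
#'
#' Stochastic EVS is Gaussian white noise low-pass filtered to a set bandwidth
#' (default 0-25 Hz) and rescaled to an exact root-mean-square amplitude.
#'
#' @param duration_s stimulus length (s).
#' @param fs sample rate (Hz).
#' @param band_hi_hz upper band edge (Hz); must be < fs/2.
#' @param target_rms_ma target RMS current (mA). The default 1.38 mA is the
#'   amplitude used during the transient-delay sessions; fixed-delay sessions
#'   used 1.47-1.61 mA.
#' @param seed RNG seed.
#' @return object of class `evs_config`.
#' @export
evs_config <- function(duration_s, fs = 2000, band_hi_hz = 25,
                       target_rms_ma = 1.38, seed = NULL) {
  if (band_hi_hz <= 0 || band_hi_hz >= fs / 2)
    stopf("band_hi_hz must be in (0, fs/2)")
  if (target_rms_ma < 0) stopf("target_rms_ma must be >= 0")
  structure(list(duration_s = duration_s, fs = fs, band_hi_hz = band_hi_hz,
                 target_rms_ma = target_rms_ma, seed = seed),
            class = "evs_config")
}

#' Generate a band-limited stochastic vestibular stimulus
#'
#' Seeded Gaussian white noise, low-pass filtered (8th-order zero-phase
#' Butterworth magnitude at the band edge), then rescaled so the sample RMS
#' equals the target exactly.
#'
#' @param cfg `evs_config`.
#' @return numeric stimulus series (mA).
#' @export
generate_evs <- function(cfg) {
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  warmup <- ceiling(4 * cfg$fs / cfg$band_hi_hz)
  if (n < warmup)
    stopf("duration too short for the 25 Hz filter warm-up (need >= %d samples)",
          warmup)
  if (cfg$target_rms_ma == 0) return(numeric(n))
  x <- with_seed(cfg$seed, rnorm(n))
  x <- fft_butterworth(x, cfg$fs, cfg$band_hi_hz, order = 8, type = "low")
  x * cfg$target_rms_ma / sqrt(mean(x^2))
}

#' Biphasic vestibular-to-EMG coupling kernel
#'
#' The vestibular-evoked muscle response is modelled as a biphasic impulse
#' response: a difference of two opposite-signed Gaussians in lag, peaking at
#' the short (~60 ms) and medium (~100 ms) latencies with widths 15 and 25 ms.
#' A time-varying `gain_schedule` in [0, 1] scales the coupling (e.g. to
#' impose attenuation during delay periods).
#'
#' @param short_ms,medium_ms peak latencies (ms).
#' @param short_width_ms,medium_width_ms Gaussian widths (ms).
#' @param amplitude kernel scale (EMG a.u. per mA per sample at the short
#'   peak; the medium lobe is matched in area).
#' @param gain_schedule function of time (s) returning a multiplier in [0, 1].
#' @return object of class `vestibular_coupling`.
#' @export
vestibular_coupling <- function(short_ms = 60, medium_ms = 100,
                                short_width_ms = 15, medium_width_ms = 25,
                                amplitude = 1,
                                gain_schedule = function(t) rep(1, length(t))) {
  structure(list(short_ms = short_ms, medium_ms = medium_ms,
                 short_width_ms = short_width_ms,
                 medium_width_ms = medium_width_ms,
                 amplitude = amplitude, gain_schedule = gain_schedule),
            class = "vestibular_coupling")
}

#' Sample the coupling kernel on a lag grid
#'
#' @param coupling `vestibular_coupling`.
#' @param fs sample rate (Hz).
#' @param max_lag_ms kernel support (ms).
#' @return numeric kernel, lag 0 at element 1. Short lobe positive, medium
#'   lobe negative (sign convention only; peaks are opposite-signed).
#' @export
coupling_kernel <- function(coupling, fs, max_lag_ms = 250) {
  lag_ms <- seq(0, max_lag_ms, by = 1000 / fs)
  g1 <- exp(-(lag_ms - coupling$short_ms)^2 / (2 * coupling$short_width_ms^2))
  g2 <- exp(-(lag_ms - coupling$medium_ms)^2 / (2 * coupling$medium_width_ms^2))
  coupling$amplitude * (g1 - g2 * coupling$short_width_ms / coupling$medium_width_ms)
}

#' Generate a vestibular-coupled EMG envelope
#'
#' envelope(t) = max(0, tonic + torque_gain * torque(t)
#'                      + gain_schedule(t) * (kernel * evs)(t) + noise)
#'
#' The convolution is causal (EMG lags the stimulus). Noise is seeded
#' Gaussian. The tonic level keeps the envelope away from the rectification
#' floor so the injected coupling survives linear analysis.
#'
#' @param trial `trial_record` providing the clock and torque channel.
#' @param evs stimulus series aligned to the trial clock (mA).
#' @param coupling `vestibular_coupling`.
#' @param tonic baseline envelope level (a.u.).
#' @param torque_gain envelope per N.m of plantar-flexor torque.
#' @param noise_std additive noise SD (a.u.).
#' @param seed RNG seed.
#' @return EMG envelope series (a.u.), nonnegative.
#' @export
generate_emg <- function(trial, evs, coupling, tonic = 10, torque_gain = 0,
                         noise_std = 1, seed = NULL) {
  n <- nrow(trial)
  if (length(evs) != n)
    stopf("length mismatch: evs has %d samples, trial %d", length(evs), n)
  fs <- trial_fs(trial)
  kern <- coupling_kernel(coupling, fs)
  drive <- causal_conv(evs, kern)
  gain_t <- coupling$gain_schedule(trial$time_s)
  if (any(gain_t < 0 | gain_t > 1)) stopf("gain_schedule must stay in [0, 1]")
  noise <- if (noise_std > 0) with_seed(seed, rnorm(n, sd = noise_std)) else 0
  pmax(0, tonic + torque_gain * trial$torque_nm + gain_t * drive + noise)
}

# causal FIR convolution: out[t] = sum_k kern[k+1] * x[t-k], zero history
causal_conv <- function(x, kern) {
  out <- convolve(x, rev(kern), type = "open")
  out[seq_along(x)]
}

#' Ground-truth perceptual observer
#'
#' Generative twin of the psychometric model: a delay period of magnitude x
#' (s) is detected with probability delta/2 + (1-delta) Phi((x-mu)/sigma).
#' Detected periods get a button press at onset + latency, with latency drawn
#' from a shifted lognormal (floor + lognormal; calibrated to the observed
#' 2-5 s detection times); latencies beyond the period are truncated to the
#' period end (still counted as detections). Occasional false presses occur
#' between periods at `false_press_rate` per minute.
#'
#' @param mu_s psychometric position (s).
#' @param sigma_s psychometric slope (s).
#' @param delta lapse probability, in [0, 0.05].
#' @param latency_meanlog,latency_sdlog lognormal parameters of the latency
#'   above the floor (log-seconds).
#' @param latency_floor_s minimum detection latency (s).
#' @param false_press_rate_per_min rate of spurious presses outside periods.
#' @return object of class `percept_truth`.
#' @export
percept_truth <- function(mu_s = 0.15, sigma_s = 0.05, delta = 0.02,
                          latency_meanlog = log(2.2), latency_sdlog = 0.5,
                          latency_floor_s = 0.5,
                          false_press_rate_per_min = 0.1) {
  if (sigma_s <= 0) stopf("sigma_s must be > 0")
  if (delta < 0 || delta > 0.05) stopf("delta must be in [0, 0.05]")
  structure(list(mu_s = mu_s, sigma_s = sigma_s, delta = delta,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 latency_floor_s = latency_floor_s,
                 false_press_rate_per_min = false_press_rate_per_min),
            class = "percept_truth")
}

#' Generate a button-state series for one session trial
#'
#' @param periods data.frame with columns `onset_s`, `delay_ms`, `duration_s`
#'   (one session trial's delay periods).
#' @param duration_s trial length (s).
#' @param truth `percept_truth`.
#' @param fs sample rate (Hz).
#' @param seed RNG seed.
#' @return integer 0/1 button series of length `duration_s * fs`.
#' @export
generate_button <- function(periods, duration_s, truth, fs = 2000,
                            seed = NULL) {
  n <- as.integer(round(duration_s * fs))
  button <- integer(n)
  with_seed(seed, {
    for (i in seq_len(nrow(periods))) {
      x <- periods$delay_ms[i] / 1000
      p <- mixture_probability(x, truth$mu_s, truth$sigma_s, truth$delta)
      if (stats::runif(1) < p) {
        lat <- truth$latency_floor_s +
          rlnorm(1, truth$latency_meanlog, truth$latency_sdlog)
        lat <- min(lat, periods$duration_s[i] - 1 / fs)
        press <- periods$onset_s[i] + lat
        release <- periods$onset_s[i] + periods$duration_s[i]
        i0 <- as.integer(round(press * fs)) + 1L
        i1 <- min(as.integer(round(release * fs)), n)
        if (i0 <= i1) button[i0:i1] <- 1L
      }
    }
    # seeded false presses in the gaps between periods
    n_false <- rpois(1, truth$false_press_rate_per_min * duration_s / 60)
    if (n_false > 0) {
      gaps_ok <- function(t) {
        all(t < periods$onset_s | t > periods$onset_s + periods$duration_s)
      }
      for (k in seq_len(n_false)) {
        t0 <- runif(1, 0, max(duration_s - 1.5, 0))
        if (gaps_ok(t0) && gaps_ok(t0 + 1)) {
          i0 <- as.integer(round(t0 * fs)) + 1L
          i1 <- min(as.integer(round((t0 + 1) * fs)), n)
          button[i0:i1] <- 1L
        }
      }
    }
  })
  button
}
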