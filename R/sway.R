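#' Extract non-overlapping 2 s analysis windows inside the balance limits
#'
#' Sway measures are computed only where the body is within the virtual
#' limits. Each maximal continuous in-limit run of length l contributes
#' floor(l / window) windows packed from the start of the run (an 11 s run
#' yields exactly five 2 s windows).
#'
#' @param theta_deg body angle series (deg).
#' @param fs sample rate (Hz).
#' @param limits `limit_config`.
#' @param window_s window length (s), default 2.
#' @return data.frame with columns `start_s`, `end_s` (class `window_set`);
#'   zero rows for an empty or never-in-limit trace.
#' @export
extract_windows <- function(theta_deg, fs, limits = limit_config(),
                            window_s = 2) {
  wlen <- as.integer(round(window_s * fs))
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  class(empty) <- c("window_set", "data.frame")
  if (!length(theta_deg)) return(empty)
  inlim <- theta_deg <= limits$anterior_limit_deg &
    theta_deg >= limits$posterior_limit_deg
  r <- rle(inlim)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    k <- r$lengths[i] %/% wlen
    if (k > 0) {
      w0 <- starts[i] + (seq_len(k) - 1L) * wlen
      out[[length(out) + 1L]] <- data.frame(
        start_s = (w0 - 1L) / fs, end_s = (w0 - 1L + wlen) / fs)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  class(res) <- c("window_set", "data.frame")
  res
}

#' Mean sway-velocity variance over 2 s windows
#'
#' The sample variance (n-1 denominator) of angular velocity is computed in
#' each window and averaged across windows: the primary instability measure.
#' Velocity comes from the trial's recorded channel, or by central finite
#' differences of angle when absent.
#'
#' @param trial `trial_record`, or a numeric theta series with `fs` given.
#' @param windows `window_set`; computed from the trial when NULL.
#' @param limits `limit_config` used when deriving windows.
#' @param fs sample rate (needed when `trial` is a bare numeric series).
#' @return list with `mean_variance` ((deg/s)^2; NA when no windows),
#'   `per_window` and `n_windows`. Never a silent zero: zero windows gives
#'   `mean_variance = NA` with `n_windows = 0`.
#' @export
sway_velocity_variance <- function(trial, windows = NULL,
                                   limits = limit_config(), fs = NULL) {
  if (inherits(trial, "trial_record")) {
    fs <- trial_fs(trial)
    theta <- trial$theta_deg
    vel <- trial$theta_dot_dps
    if (all(vel == 0)) vel <- central_diff(theta, fs)
  } else {
    if (is.null(fs)) stopf("fs required for a bare numeric series")
    theta <- trial
    vel <- central_diff(theta, fs)
  }
  if (is.null(windows)) windows <- extract_windows(theta, fs, limits)
  if (nrow(windows) == 0L)
    return(list(mean_variance = NA_real_, per_window = numeric(0),
                n_windows = 0L))
  pv <- vapply(seq_len(nrow(windows)), function(i) {
    i0 <- as.integer(round(windows$start_s[i] * fs)) + 1L
    i1 <- as.integer(round(windows$end_s[i] * fs))
    stats::var(vel[i0:i1])
  }, numeric(1))
  list(mean_variance = mean(pv), per_window = pv, n_windows = length(pv))
}

#' Percentage of time within the virtual balance limits
#'
#' @param theta_deg body angle series (deg).
#' @param fs sample rate (Hz).
#' @param limits `limit_config`.
#' @param interval_s reporting interval (s), default 60; one value per full
#'   interval.
#' @param allow_partial include a trailing partial interval (and accept traces
#'   shorter than one interval).
#' @return numeric vector of percentages, one per interval.
#' @export
percent_within_limits <- function(theta_deg, fs, limits = limit_config(),
                                  interval_s = 60, allow_partial = FALSE) {
  n <- length(theta_deg)
  ilen <- as.integer(round(interval_s * fs))
  if (n < ilen && !allow_partial)
    stopf("trace shorter than one %g s interval; set allow_partial = TRUE",
          interval_s)
  inlim <- theta_deg <= limits$anterior_limit_deg &
    theta_deg >= limits$posterior_limit_deg
  n_int <- if (allow_partial) ceiling(n / ilen) else n %/% ilen
  vapply(seq_len(n_int), function(i) {
    idx <- ((i - 1L) * ilen + 1L):min(i * ilen, n)
    100 * mean(inlim[idx])
  }, numeric(1))
}

#' Sliding-window sway-velocity variance
#'
#' Centered moving sample variance over a 2 s window, one value per sample
#' (the movvar-style time course used to track instability around delay
#' transitions). Edge windows shrink symmetrically rather than pad, so the
#' trace starts responding up to one window half-width before an event.
#'
#' @param x angular-velocity series (deg/s).
#' @param fs sample rate (Hz).
#' @param window_s window length (s).
#' @return variance series, same length as `x`.
#' @export
sliding_velocity_variance <- function(x, fs, window_s = 2) {
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  if (n <= w) stopf("series must be longer than the window")
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i0 <- pmax(seq_len(n) - half, 1L)
  i1 <- pmin(seq_len(n) + (w - half - 1L), n)
  m <- i1 - i0 + 1L
  s <- cs[i1 + 1L] - cs[i0]
  s2 <- cs2[i1 + 1L] - cs2[i0]
  v <- (s2 - s^2 / m) / (m - 1)
  pmax(v, 0)
}

#' Peak sway-velocity variance between delay onset and detection
#'
#' @param variance_series output of [sliding_velocity_variance()].
#' @param fs sample rate (Hz).
#' @param onset_s delay-period onset (s).
#' @param press_s detection (button press) time (s); must exceed `onset_s` --
#'   transitions with a press at or before onset are excluded upstream.
#' @return peak variance ((deg/s)^2) on [onset, press].
#' @export
peak_variance_before_detection <- function(variance_series, fs, onset_s,
                                           press_s) {
  if (press_s <= onset_s)
    stopf("excluded transition: press (%.3f s) precedes onset (%.3f s)",
          press_s, onset_s)
  i0 <- max(as.integer(round(onset_s * fs)) + 1L, 1L)
  i1 <- min(as.integer(round(press_s * fs)) + 1L, length(variance_series))
  max(variance_series[i0:i1])
}

#' Fit a first-order exponential f(x) = a exp(-x/b) + c
#'
#' Least squares with the amplitude and offset profiled out analytically
#' (linear given b) and the time constant b found on a multi-start
#' logarithmic grid refined by golden-section search -- deterministic and
#' robust to the usual exponential-fit initialization trap.
#'
#' @param x strictly increasing abscissa (time, minutes or seconds).
#' @param y observed values.
#' @return object of class `exp_fit`: a, b, c, residual norm, `value_at_tc`
#'   (= a/e + c, the value at one time constant), landmarks `t63 = b` and
#'   `t95 = 3 b`, and `identifiable` (FALSE for degenerate/constant data or a
#'   boundary time constant).
#' @export
fit_exponential <- function(x, y) {
  if (length(x) < 4L) stopf("need at least 4 points")
  if (any(diff(x) <= 0)) stopf("x must be strictly increasing")
  xr <- diff(range(x))
  x0 <- x - min(x)
  rss_of <- function(b) {
    e <- exp(-x0 / b)
    fit <- stats::lm.fit(cbind(e, 1), y)
    sum(fit$residuals^2)
  }
  grid <- exp(seq(log(xr / 100), log(xr * 10), length.out = 60))
  rss <- vapply(grid, rss_of, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  b <- stats::optimize(rss_of, c(lo, hi))$minimum
  e <- exp(-x0 / b)
  co <- stats::lm.fit(cbind(e, 1), y)$coefficients
  a <- unname(co[1]); cc <- unname(co[2])
  # shift a back to the original x origin
  a <- a * exp(min(x) / b)
  resid <- y - (a * exp(-x / b) + cc)
  sdy <- stats::sd(y)
  identifiable <- is.finite(a) && sdy > 0 && abs(a) > 1e-8 * max(sdy, 1) &&
    b > grid[1] * 1.0001 && b < grid[length(grid)] * 0.9999
  structure(list(a = a, b = b, c = cc,
                 residual = sqrt(sum(resid^2)),
                 value_at_tc = a * exp(-1) + cc,
                 t63 = b, t95 = 3 * b,
                 identifiable = identifiable),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> f(x) = %.4g * exp(-x/%.4g) + %.4g  (value at tc: %.4g%s)\n",
    x$a, x$b, x$c, x$value_at_tc,
    if (x$identifiable) "" else "; UNIDENTIFIABLE"))
  invisible(x)
}

#' Percent attenuation of the decaying component at time t
#'
#' 100 (1 - exp(-t/b)) relative to the decaying amplitude: 63.2% at t = b,
#' 95% at t = 3b.
#'
#' @param fit `exp_fit`.
#' @param t time since decay onset (same units as the fit's x).
#' @return percent reduction.
#' @export
attenuation_at <- function(fit, t) {
  if (!fit$identifiable) stopf("attenuation undefined: fit is unidentifiable")
  100 * (1 - exp(-t / fit$b))
}
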