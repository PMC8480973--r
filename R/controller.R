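#' Delayed proportional-derivative balance controller
#'
#' A minimal stand-in for the human balancer: ankle torque is a PD law on the
#' body state sensed through an intrinsic sensorimotor delay (default 120 ms,
#' within the physiological 100-160 ms range), plus band-limited Gaussian
#' torque noise that drives realistic sway in the stable regime.
#'
#' @param kp proportional gain (N.m/rad); must exceed the gravitational
#'   stiffness mm g L for the loop to be stabilizable.
#' @param kd derivative gain (N.m.s/rad).
#' @param intrinsic_delay_ms sensing delay (ms).
#' @param noise_std standard deviation of the torque noise (N.m) after
#'   band-limiting.
#' @param noise_bandwidth_hz low-pass bandwidth of the torque noise (Hz).
#' @param seed RNG seed for the noise stream.
#' @return object of class `controller_params`.
#' @export
controller_params <- function(kp = 690, kd = 120, intrinsic_delay_ms = 120,
                              noise_std = 1, noise_bandwidth_hz = 5,
                              seed = NULL) {
  if (intrinsic_delay_ms < 0) stopf("intrinsic_delay_ms must be >= 0")
  if (noise_std < 0) stopf("noise_std must be >= 0")
  structure(list(kp = kp, kd = kd, intrinsic_delay_ms = intrinsic_delay_ms,
                 noise_std = noise_std, noise_bandwidth_hz = noise_bandwidth_hz,
                 seed = seed), class = "controller_params")
}

#' PD torque from a (delayed) sensed state
#'
#' @param theta_deg sensed body angle (deg).
#' @param theta_dot_dps sensed angular velocity (deg/s).
#' @param ctrl `controller_params`.
#' @param params `pendulum_params`; used to warn when kp cannot stabilize.
#' @return ankle torque (N.m), noise-free.
#' @export
pd_torque <- function(theta_deg, theta_dot_dps, ctrl, params = NULL) {
  if (!is.null(params) && ctrl$kp <= grav_stiffness(params))
    warning(sprintf(
      "kp = %.1f <= mm g L = %.1f N.m/rad: loop cannot be stable",
      ctrl$kp, grav_stiffness(params)), call. = FALSE)
  -ctrl$kp * theta_deg * DEG2RAD - ctrl$kd * theta_dot_dps * DEG2RAD
}

# band-limited torque noise, exact target sd after filtering
make_torque_noise <- function(n, fs, noise_std, bandwidth_hz, seed) {
  if (noise_std == 0) return(numeric(n))
  x <- with_seed(seed, rnorm(n))
  x <- fft_butterworth(x, fs, bandwidth_hz, order = 4, type = "low")
  x * noise_std / stats::sd(x)
}

# normalize a delay schedule to a per-sample vector of imposed delays (ms)
schedule_to_samples <- function(delay_schedule, n, fs) {
  if (is.numeric(delay_schedule) && length(delay_schedule) == 1L)
    delay_schedule <- data.frame(time_s = 0, delay_ms = delay_schedule)
  if (is.null(delay_schedule$time_s) || is.null(delay_schedule$delay_ms))
    stopf("delay_schedule needs columns time_s and delay_ms")
  sch <- delay_schedule[order(delay_schedule$time_s), , drop = FALSE]
  if (sch$time_s[1] > 0)
    stopf("delay schedule has a gap: it must cover t = 0")
  idx <- findInterval((seq_len(n) - 1) / fs, sch$time_s)
  sch$delay_ms[idx]
}

#' Simulate the closed loop of plant, limits and delayed PD controller
#'
#' Runs the balance simulation: the controller senses the state through its
#' intrinsic delay, its torque reaches the plant through the 20 ms motor delay
#' plus the scheduled imposed delay, and the virtual limit mechanics act each
#' step. Fully seeded and reproducible.
#'
#' @param params `pendulum_params`.
#' @param limits `limit_config`, or NULL to disable the virtual limits
#'   (useful for stability-margin probing).
#' @param ctrl `controller_params`.
#' @param delay_schedule either a single imposed delay (ms) or a data.frame
#'   with columns `time_s`, `delay_ms` (piecewise-constant from each time on;
#'   must cover t = 0).
#' @param duration_s trial length (s).
#' @param seed RNG seed (overrides `ctrl$seed` when given).
#' @param motor_delay_ms fixed actuation delay of the robot (ms).
#' @param theta0_deg initial lean (deg).
#' @return object of class `closed_loop_result`: `trial` (a [trial_record()]),
#'   `limit_crossings` (entries into the beyond-limit region) and `diverged`.
#' @export
run_closed_loop <- function(params, limits, ctrl, delay_schedule,
                            duration_s, seed = ctrl$seed,
                            motor_delay_ms = 20, theta0_deg = 0) {
  fs <- params$fs
  n <- as.integer(round(duration_s * fs))
  imposed <- schedule_to_samples(delay_schedule, n, fs)
  tds <- as.integer(round((imposed + motor_delay_ms) * fs / 1000))
  intr <- as.integer(round(ctrl$intrinsic_delay_ms * fs / 1000))
  noise <- make_torque_noise(n, fs, ctrl$noise_std, ctrl$noise_bandwidth_hz,
                             seed)
  zoh <- zoh_discretize(params)
  use_limits <- !is.null(limits)
  if (!use_limits) limits <- limit_config(params)
  sim <- simulate_loop_cpp(
    n, zoh$Ad[1, 1], zoh$Ad[1, 2], zoh$Ad[2, 1], zoh$Ad[2, 2],
    zoh$Bd[1], zoh$Bd[2], ctrl$kp, ctrl$kd, intr, tds, noise,
    limits$anterior_limit_deg * DEG2RAD, limits$posterior_limit_deg * DEG2RAD,
    limits$ramp_deg * DEG2RAD, limits$support_torque_nm, limits$damping_nms,
    limits$barrier_gain, use_limits, theta0_deg * DEG2RAD, 0)

  theta_deg <- sim$theta * RAD2DEG
  crossings <- sum(diff(c(FALSE, sim$engaged)) == 1L)
  diverged <- if (use_limits) {
    tail_idx <- seq.int(max(1L, n - as.integer(fs * 5)), n)
    mean(sim$engaged[tail_idx]) > 0.5
  } else {
    any(abs(theta_deg) > 30)
  }
  trial <- trial_record(
    time_s = (seq_len(n) - 1) / fs,
    theta_deg = theta_deg,
    theta_dot_dps = sim$theta_dot * RAD2DEG,
    torque_nm = sim$torque,
    delay_ms = imposed,
    fs = fs,
    meta = list(seed = seed, kp = ctrl$kp, kd = ctrl$kd,
                intrinsic_delay_ms = ctrl$intrinsic_delay_ms,
                motor_delay_ms = motor_delay_ms))
  ds_log("simulate", n = n, crossings = crossings, diverged = diverged)
  if (diverged && use_limits && crossings == 0L) crossings <- 1L
  structure(list(trial = trial, limit_crossings = crossings,
                 diverged = diverged),
            class = "closed_loop_result")
}

#' Retune PD gains for an imposed delay
#'
#' Emulates training: a reproducible coordinate grid search over (kp, kd)
#' minimizing the mean sway-velocity variance across seeded evaluation trials
#' at the given imposed delay.
#'
#' @param params `pendulum_params`.
#' @param limits `limit_config`.
#' @param ctrl starting `controller_params` (noise settings are kept).
#' @param imposed_delay_ms imposed delay to tune at (ms).
#' @param kp_grid,kd_grid candidate gain values; defaults span a bounded box
#'   around the plant's gravitational stiffness.
#' @param duration_s evaluation trial length (s).
#' @param seeds evaluation seeds (variance averaged across them).
#' @return `controller_params` with the best gains; attributes `objective`
#'   (achieved mean variance, (deg/s)^2) and `diverged` (TRUE when no
#'   candidate kept the loop in the limits).
#' @export
retune_gains <- function(params, limits, ctrl, imposed_delay_ms,
                         kp_grid = NULL, kd_grid = NULL,
                         duration_s = 30, seeds = 1:2) {
  k0 <- grav_stiffness(params)
  if (is.null(kp_grid)) kp_grid <- k0 * c(1.2, 1.5, 2, 3)
  if (is.null(kd_grid)) kd_grid <- sqrt(params$I * k0) * c(0.4, 0.8, 1.5, 2.5)
  best <- NULL
  for (kp in kp_grid) for (kd in kd_grid) {
    cand <- controller_params(kp = kp, kd = kd,
                              intrinsic_delay_ms = ctrl$intrinsic_delay_ms,
                              noise_std = ctrl$noise_std,
                              noise_bandwidth_hz = ctrl$noise_bandwidth_hz)
    vals <- vapply(seeds, function(s) {
      res <- run_closed_loop(params, limits, cand, imposed_delay_ms,
                             duration_s, seed = s)
      v <- sway_velocity_variance(res$trial, limits = limits)
      if (is.na(v$mean_variance)) Inf else v$mean_variance
    }, numeric(1))
    obj <- mean(vals)
    if (is.null(best) || obj < best$obj)
      best <- list(obj = obj, ctrl = cand)
  }
  out <- best$ctrl
  attr(out, "objective") <- best$obj
  attr(out, "diverged") <- !is.finite(best$obj)
  out
}

#' Largest stabilizable imposed delay, by bisection
#'
#' Probes the closed loop (limits disabled, small initial lean, noise off) and
#' bisects on the imposed delay for the divergence boundary.
#'
#' @inheritParams run_closed_loop
#' @param lo,hi bracket (ms); `hi` is assumed diverging.
#' @param tol_ms bisection tolerance (ms).
#' @return largest non-diverging imposed delay found (ms).
#' @export
stability_margin <- function(params, ctrl, lo = 0, hi = 600, tol_ms = 10,
                             duration_s = 20) {
  quiet <- controller_params(kp = ctrl$kp, kd = ctrl$kd,
                             intrinsic_delay_ms = ctrl$intrinsic_delay_ms,
                             noise_std = 0)
  div_at <- function(d)
    run_closed_loop(params, NULL, quiet, d, duration_s,
                    theta0_deg = 0.5)$diverged
  if (div_at(lo)) return(NA_real_)
  while (hi - lo > tol_ms) {
    mid <- (lo + hi) / 2
    if (div_at(mid)) hi <- mid else lo <- mid
  }
  lo
}
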