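#' Inverted-pendulum plant parameters
#'
#' Parameterizes the linearized single-link inverted pendulum used by the
#' robotic balance simulator: I.theta'' - mm.g.L.theta = T, where theta is the
#' whole-body angle about the ankles (positive = anterior lean), T is ankle
#' torque, mm = 0.971 m is the effective moving mass (total mass minus feet),
#' L the height of the centre of mass above the ankles, and I = mm L^2 the
#' moment of inertia about the ankles.
#'
#' @param mass_kg total body mass m (kg).
#' @param com_height_m centre-of-mass height L (m).
#' @param gravity gravitational acceleration (m/s^2).
#' @param sample_rate_hz real-time update rate fs (Hz); >= 100. The default
#'   2000 Hz matches the real-time controller; 200 Hz is a useful decimated
#'   mode for fast tests (the zero-order-hold update is recomputed per dt).
#' @return object of class `pendulum_params` with fields m, mm, L, g, I, fs.
#' @export
pendulum_params <- function(mass_kg = 75, com_height_m = 0.95,
                            gravity = 9.81, sample_rate_hz = 2000) {
  if (mass_kg <= 0 || com_height_m <= 0 || gravity <= 0)
    stopf("mass, height and gravity must be strictly positive")
  if (sample_rate_hz < 100) stopf("sample_rate_hz must be >= 100")
  mm <- 0.971 * mass_kg
  structure(list(
    m = mass_kg, mm = mm, L = com_height_m, g = gravity,
    I = mm * com_height_m^2, fs = sample_rate_hz
  ), class = "pendulum_params")
}

# gravitational stiffness mm*g*L (N.m/rad), the toppling-torque slope
grav_stiffness <- function(params) params$mm * params$g * params$L

#' Exact zero-order-hold discretization of the pendulum
#'
#' Returns the discrete state-transition matrix Ad and input vector Bd such
#' that x[k+1] = Ad x[k] + Bd T[k] for x = (theta, theta_dot) in radians and
#' torque held constant over each sample interval. This is the matrix
#' exponential of the continuous system (cosh/sinh form for the unstable
#' pendulum), not an Euler approximation.
#'
#' @param params `pendulum_params`.
#' @param dt sample interval (s); defaults to 1/fs.
#' @return list(Ad = 2x2 matrix, Bd = length-2 vector, dt).
#' @export
zoh_discretize <- function(params, dt = 1 / params$fs) {
  w2 <- params$g / params$L           # mm*g*L / I reduces to g/L
  w <- sqrt(w2)
  ch <- cosh(w * dt); sh <- sinh(w * dt)
  Ad <- matrix(c(ch, w * sh, sh / w, ch), 2, 2)  # column-major
  Bd <- c((ch - 1) / w2, sh / w) / params$I
  list(Ad = Ad, Bd = Bd, dt = dt)
}

#' Advance the pendulum one sample under constant torque
#'
#' @param state list with `theta` (rad, positive anterior), `theta_dot`
#'   (rad/s) and `time` (s).
#' @param torque ankle torque (N.m) held over the interval.
#' @param params `pendulum_params`.
#' @param zoh optional precomputed result of [zoh_discretize()] (avoids
#'   recomputation in loops).
#' @return updated state list.
#' @export
step_pendulum <- function(state, torque, params, zoh = zoh_discretize(params)) {
  check_finite(c(state$theta, state$theta_dot), "state")
  check_finite(torque, "torque")
  x <- c(state$theta, state$theta_dot)
  xn <- drop(zoh$Ad %*% x) + zoh$Bd * torque
  list(theta = xn[1], theta_dot = xn[2], time = state$time + zoh$dt)
}

#' Virtual angular limit configuration
#'
#' The balance simulator imposes virtual position limits (default 6 deg
#' anterior, -3 deg posterior). Beyond a limit a passive supportive torque
#' ramps linearly from zero at the limit to `support_torque_nm` at `ramp_deg`
#' beyond it (passively holding the body at the secondary limit), plus a
#' velocity-damping term active only beyond the limit so motion attenuates
#' smoothly rather than hitting a hard stop.
#'
#' `support_torque_nm` defaults to the gravitational toppling torque at the
#' secondary limit, mm g L sin(limit + ramp): the torque the support must
#' cancel to hold the body there. `damping_nms` defaults to the critical
#' damping scale 2 sqrt(I mm g L).
#'
#' @param params `pendulum_params` used for the defaults.
#' @param anterior_limit_deg positive anterior limit (deg).
#' @param posterior_limit_deg negative posterior limit (deg).
#' @param ramp_deg width of the linear supportive-torque ramp (deg).
#' @param support_torque_nm supportive-torque threshold (N.m); optional.
#' @param damping_nms damping coefficient (N.m.s/rad); optional.
#' @param barrier_gain stiffness multiplier past the secondary limit; the
#'   ramp slope steepens by this factor so bounded torques cannot push the
#'   body appreciably beyond the secondary limits.
#' @return object of class `limit_config`.
#' @export
limit_config <- function(params = pendulum_params(),
                         anterior_limit_deg = 6, posterior_limit_deg = -3,
                         ramp_deg = 1, support_torque_nm = NULL,
                         damping_nms = NULL, barrier_gain = 20) {
  if (!(anterior_limit_deg > 0 && posterior_limit_deg < 0))
    stopf("need anterior_limit_deg > 0 > posterior_limit_deg")
  if (ramp_deg <= 0) stopf("ramp_deg must be > 0")
  if (is.null(support_torque_nm)) {
    lim <- max(anterior_limit_deg, -posterior_limit_deg) + ramp_deg
    support_torque_nm <- grav_stiffness(params) * sin(lim * DEG2RAD)
  }
  if (support_torque_nm <= 0) stopf("support_torque_nm must be > 0")
  if (is.null(damping_nms))
    damping_nms <- 2 * sqrt(params$I * grav_stiffness(params))
  structure(list(
    anterior_limit_deg = anterior_limit_deg,
    posterior_limit_deg = posterior_limit_deg,
    ramp_deg = ramp_deg,
    support_torque_nm = support_torque_nm,
    damping_nms = damping_nms,
    barrier_gain = barrier_gain
  ), class = "limit_config")
}

#' Supportive torque from the virtual limits
#'
#' Zero inside the limits; beyond a limit, a restoring torque ramping linearly
#' to `support_torque_nm` at `ramp_deg` past the limit, plus damping opposing
#' angular velocity, active only beyond the limit. Past the secondary limit
#' the simulated stiffness keeps growing (slope multiplied by `barrier_gain`)
#' so the body cannot rotate further regardless of the ankle torque applied --
#' the virtual limits are a constraint, not a finite spring.
#'
#' @param theta_deg body angle (deg, positive anterior); vectorized.
#' @param theta_dot_dps angular velocity (deg/s); recycled.
#' @param cfg `limit_config`.
#' @return supportive torque (N.m), sign opposing further excursion.
#' @export
limit_torque <- function(theta_deg, theta_dot_dps = 0, cfg = limit_config()) {
  n <- max(length(theta_deg), length(theta_dot_dps))
  th <- rep_len(theta_deg, n); thd <- rep_len(theta_dot_dps, n)
  out <- numeric(n)
  damp_dps <- cfg$damping_nms * DEG2RAD    # N.m per deg/s
  ramp <- function(exc_deg) {
    frac <- pmin(exc_deg / cfg$ramp_deg, 1)
    over <- pmax(exc_deg - cfg$ramp_deg, 0)
    cfg$support_torque_nm * (frac + cfg$barrier_gain * over / cfg$ramp_deg)
  }
  ant <- th > cfg$anterior_limit_deg
  if (any(ant))
    out[ant] <- -ramp(th[ant] - cfg$anterior_limit_deg) - damp_dps * thd[ant]
  post <- th < cfg$posterior_limit_deg
  if (any(post))
    out[post] <- ramp(cfg$posterior_limit_deg - th[post]) - damp_dps * thd[post]
  out
}

#' Torque delay line
#'
#' Models the simulator's torque buffer: output torque at time t is the torque
#' recorded at t - delay. Before t = delay the buffer returns the pre-trial
#' hold value (zero net torque). Sub-sample delays round to the nearest sample
#' (0.5 ms at 2000 Hz).
#'
#' @param delay_ms imposed delay (ms).
#' @param fs sample rate (Hz).
#' @param capacity_ms buffer capacity (ms); must be >= 500 and >= delay.
#' @return object of class `delay_line`.
#' @export
delay_line <- function(delay_ms, fs = 2000, capacity_ms = max(500, delay_ms)) {
  if (capacity_ms < 500) stopf("delay-line capacity must be >= 500 ms")
  if (delay_ms < 0 || delay_ms > capacity_ms)
    stopf("delay %.1f ms outside [0, capacity = %.0f ms]", delay_ms, capacity_ms)
  structure(list(delay_ms = delay_ms, fs = fs, capacity_ms = capacity_ms,
                 delay_samples = as.integer(round(delay_ms * fs / 1000))),
            class = "delay_line")
}

#' Read a delayed torque series through a delay line
#'
#' @param line `delay_line`.
#' @param torque recorded torque series (N.m), sample i at time (i-1)/fs.
#' @param t optional time (s) at which to read a single value; if NULL the
#'   whole delayed series is returned.
#' @param hold pre-trial hold value returned before t = delay.
#' @return delayed torque value or series.
#' @export
delayed_torque <- function(line, torque, t = NULL, hold = 0) {
  d <- line$delay_samples
  if (is.null(t)) {
    n <- length(torque)
    if (d == 0L) return(torque)
    return(c(rep(hold, min(d, n)), torque[seq_len(max(n - d, 0L))]))
  }
  if (t < 0) stopf("t must be >= 0")
  i <- as.integer(round(t * line$fs)) + 1L - d
  if (i < 1L) hold else torque[i]
}

#' Fit and apply the 6-point linear visual-motion predictor
#'
#' The simulator's visual scene lags the motors; a linear least-squares
#' predictor extrapolates sway a fixed horizon ahead from the last six
#' samples. `fit_predictor` learns the six weights by regressing training
#' sway, shifted by the horizon, on its own recent history.
#'
#' @param theta training sway series (deg).
#' @param horizon_ms prediction horizon (ms).
#' @param fs sample rate (Hz).
#' @param n_points history length (default 6 samples).
#' @return numeric weight vector w (oldest sample first) such that the
#'   prediction is sum(w * samples).
#' @export
fit_predictor <- function(theta, horizon_ms, fs, n_points = 6L) {
  h <- as.integer(round(horizon_ms * fs / 1000))
  n <- length(theta)
  if (n < n_points + h + 1L) stopf("training series too short for the horizon")
  X <- stats::embed(theta[seq_len(n - h)], n_points)   # cols: newest..oldest
  y <- theta[(n_points + h):n]
  w <- qr.coef(qr(X), y)
  w[is.na(w)] <- 0
  rev(unname(w))                                       # oldest first
}

#' @rdname fit_predictor
#' @param samples the last `n_points` sway samples, oldest first.
#' @param coeffs weights from [fit_predictor()].
#' @return predicted sway angle (deg) at the horizon.
#' @export
predict_forward <- function(samples, coeffs) {
  if (length(samples) < length(coeffs))
    stopf("insufficient history: need %d samples, got %d",
          length(coeffs), length(samples))
  check_finite(samples, "samples")
  sum(utils::tail(samples, length(coeffs)) * coeffs)
}
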