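# shared fixtures: small, fast configurations used across test files

fast_params <- function(fs = 200) pendulum_params(sample_rate_hz = fs)

fast_limits <- function(params = fast_params()) limit_config(params)

# analytic propagation of the linearized pendulum under piecewise-constant
# torque, written directly from the scalar closed form (independent of the
# package's matrix ZOH code path)
analytic_piecewise <- function(theta0, theta_dot0, torques, params) {
  w <- sqrt(params$g / params$L)
  dt <- 1 / params$fs
  k <- params$mm * params$g * params$L
  th <- theta0; thd <- theta_dot0
  for (T in torques) {
    # particular solution theta_p = -T/k; homogeneous cosh/sinh about it
    d <- th + T / k
    th_new <- -T / k + d * cosh(w * dt) + (thd / w) * sinh(w * dt)
    thd_new <- d * w * sinh(w * dt) + thd * cosh(w * dt)
    th <- th_new; thd <- thd_new
  }
  c(theta = th, theta_dot = thd)
}

# brute-force spectra by the textbook per-segment definition (oracle for the
# vectorized segment_spectra implementation)
brute_spectra <- function(s, r, nfft, fs) {
  s <- s - mean(s); r <- r - mean(r)
  L <- length(s) %/% nfft
  Pss <- Prr <- numeric(nfft); Psr <- complex(nfft)
  for (k in seq_len(L)) {
    idx <- ((k - 1) * nfft + 1):(k * nfft)
    S <- fft(s[idx]); R <- fft(r[idx])
    Pss <- Pss + Mod(S)^2 / nfft
    Prr <- Prr + Mod(R)^2 / nfft
    Psr <- Psr + Conj(S) * R / nfft
  }
  list(Pss = Pss / L, Prr = Prr / L, Psr = Psr / L, L = L)
}

# a coupled stimulus/response pair with known scalar gain plus noise
coupled_pair <- function(n, gain = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- gain * x + rnorm(n, sd = noise_sd)
  list(x = x, y = y)
}
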