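#' @useDynLib delaystand, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm var sd median qnorm pnorm rbinom rlnorm runif
#'   rpois lm coef optimize quantile convolve
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and stream index, staying < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stopf("non-finite values in channel '%s'", name)
  invisible(x)
}

#' Zero-phase Butterworth-magnitude filter
#'
#' Applies the magnitude response of an order-`order` Butterworth low- or
#' high-pass filter with zero phase, implemented in the frequency domain with
#' reflection padding. For `squared = TRUE` the squared magnitude of an
#' order-`order/2` filter is applied, i.e. the response of a forward-backward
#' (filtfilt) cascade whose overall attenuation order is `order`.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz).
#' @param order overall filter order (attenuation slope order).
#' @param type "low" or "high".
#' @param squared if TRUE (default) interpret `order` as the overall order of a
#'   zero-lag forward-backward cascade; if FALSE apply the order-`order`
#'   magnitude twice (the stricter alternative reading of "order-n, zero lag").
#' @return filtered numeric vector, same length as `x`.
#' @export
fft_butterworth <- function(x, fs, cutoff, order, type = c("low", "high"),
                            squared = TRUE) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 8L) stopf("signal too short to filter (n = %d)", n)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stopf("cutoff %.3g Hz outside (0, fs/2)", cutoff)
  # reflect-pad to suppress circular wrap-around at the edges
  pad <- min(n, max(64L, ceiling(4 * fs / cutoff)))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1L]))
  np <- length(xp)
  f <- (seq_len(np) - 1L) / np * fs
  f <- pmin(f, fs - f)                    # two-sided frequency magnitude
  ratio <- if (type == "low") f / cutoff else
    ifelse(f > 0, cutoff / f, Inf)
  # |H_m(f)|^2 with m = order/2 gives overall order `order`; otherwise |H_order|^2
  expo <- if (squared) order else 2 * order
  gain <- 1 / (1 + ratio^expo)
  y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / np
  y[pad + seq_len(n)]
}

# centered finite-difference derivative (deg -> deg/s)
central_diff <- function(x, fs) {
  n <- length(x)
  if (n < 3L) stopf("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# structured single-line log record; silenced unless option delaystand.verbose
ds_log <- function(stage, ...) {
  fields <- list(...)
  entry <- c(list(stage = stage, ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             fields)
  if (isTRUE(getOption("delaystand.verbose", FALSE)))
    message(jsonlite::toJSON(entry, auto_unbox = TRUE))
  invisible(entry)
}
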