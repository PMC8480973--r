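#' Classify button responses against delay periods
#'
#' A period is `detected` if the button was pressed at any time during it,
#' `missed` if not, and `excluded` if the button was already pressed before
#' the onset and held into the period (the press cannot be attributed to the
#' delay). Detection time is the first press within the period, relative to
#' onset.
#'
#' @param button 0/1 button series.
#' @param fs sample rate (Hz).
#' @param periods data.frame with `onset_s`, `delay_ms`, `duration_s`;
#'   periods must not overlap.
#' @return data.frame (class `period_outcomes`) with `delay_ms`, `status`
#'   (detected / missed / excluded) and `detection_time_s` (NA unless
#'   detected).
#' @export
classify_periods <- function(button, fs, periods) {
  p <- periods[order(periods$onset_s), , drop = FALSE]
  if (nrow(p) > 1L &&
      any(p$onset_s[-1] < (p$onset_s + p$duration_s)[-nrow(p)]))
    stopf("design error: overlapping delay periods")
  out <- data.frame(delay_ms = p$delay_ms,
                    status = character(nrow(p)),
                    detection_time_s = NA_real_)
  for (i in seq_len(nrow(p))) {
    i_on <- as.integer(round(p$onset_s[i] * fs)) + 1L
    i_off <- min(as.integer(round((p$onset_s[i] + p$duration_s[i]) * fs)),
                 length(button))
    if (i_on > length(button)) { out$status[i] <- "missed"; next }
    if (button[i_on] == 1L) {            # held from before the onset
      out$status[i] <- "excluded"
      next
    }
    idx <- which(button[i_on:i_off] == 1L)
    if (length(idx)) {
      out$status[i] <- "detected"
      out$detection_time_s[i] <- (idx[1] - 1L) / fs
    } else out$status[i] <- "missed"
  }
  class(out) <- c("period_outcomes", "data.frame")
  out
}

#' Per-delay detection table
#'
#' Excluded periods leave the denominator; percentages are rounded to the
#' nearest integer for display while the exact fraction is retained for
#' fitting. Levels with every period excluded are reported with a zero
#' denominator, never silently dropped.
#'
#' @param outcomes `period_outcomes` (rows from one or more sessions).
#' @return data.frame with `delay_ms`, `presented`, `excluded`, `used`,
#'   `detected`, `fraction`, `percent` (integer display),
#'   `mean_detection_time_s`.
#' @export
detection_table <- function(outcomes) {
  lv <- sort(unique(outcomes$delay_ms))
  rows <- lapply(lv, function(d) {
    o <- outcomes[outcomes$delay_ms == d, , drop = FALSE]
    excl <- sum(o$status == "excluded")
    used <- nrow(o) - excl
    det <- sum(o$status == "detected")
    frac <- if (used > 0) det / used else NA_real_
    data.frame(delay_ms = d, presented = nrow(o), excluded = excl,
               used = used, detected = det, fraction = frac,
               percent = if (is.na(frac)) NA_integer_ else
                 as.integer(round(100 * frac)),
               mean_detection_time_s =
                 if (det > 0) mean(o$detection_time_s[o$status == "detected"])
                 else NA_real_)
  })
  do.call(rbind, rows)
}

#' Lapse-mixture psychometric detection probability
#'
#' p(x | mu, sigma, delta) = delta/2 + (1 - delta) Phi((x - mu)/sigma):
#' a cumulative-normal psychometric function mixed with a lapse process that
#' pushes the asymptotes to delta/2 and 1 - delta/2.
#'
#' @param x delay magnitude (s); vectorized.
#' @param mu position of the sigmoid (s).
#' @param sigma slope parameter (s); must be > 0.
#' @param delta lapse probability in [0, 1].
#' @return detection probability.
#' @export
mixture_probability <- function(x, mu, sigma, delta) {
  if (any(sigma <= 0)) stopf("sigma must be > 0")
  if (any(delta < 0 | delta > 1)) stopf("delta must be in [0, 1]")
  delta / 2 + (1 - delta) * pnorm((x - mu) / sigma)
}

#' Bayesian psychometric fit on the printed grids
#'
#' Binomial likelihood of the per-level detected/used counts under the
#' lapse-mixture model, uniform prior over the full (mu, sigma, delta) grid
#' (defaults exactly as used in the study: mu 0-0.5 s step 0.005, sigma
#' 0.01-5 step 0.01, delta 0.01-0.05 step 0.01), computed in log space.
#' The lapse rate delta is marginalized out to give the joint posterior over
#' (mu, sigma); the best-fitting curve is the posterior mode, and the
#' reported threshold is the posterior-averaged interpolated 70% point
#' ([threshold70()]).
#'
#' @param counts data.frame with `delay_s` (or `delay_ms`), `detected`,
#'   `used`; needs >= 2 distinct levels.
#' @param mu_grid,sigma_grid,delta_grid parameter grids.
#' @param delta_for_threshold "posterior" (default: posterior-mean delta per
#'   (mu, sigma) cell enters the 70% interpolation) or "mid" (fixed mid-grid
#'   delta = 0.03).
#' @return object of class `psychometric_posterior`: grids, `joint`
#'   (mu x sigma posterior, sums to 1), `mode` (mu, sigma at the maximum,
#'   with an `at_edge` flag), `threshold70_s`, and the per-cell threshold
#'   matrix used for posterior summaries.
#' @export
fit_psychometric <- function(counts,
                             mu_grid = seq(0, 0.5, by = 0.005),
                             sigma_grid = seq(0.01, 5, by = 0.01),
                             delta_grid = seq(0.01, 0.05, by = 0.01),
                             delta_for_threshold = c("posterior", "mid")) {
  delta_for_threshold <- match.arg(delta_for_threshold)
  if (is.null(counts$delay_s)) {
    if (is.null(counts$delay_ms)) stopf("counts needs delay_s or delay_ms")
    counts$delay_s <- counts$delay_ms / 1000
  }
  counts <- counts[counts$used > 0, , drop = FALSE]
  if (nrow(counts) < 2L) stopf("need counts at >= 2 delay levels")
  nm <- length(mu_grid); ns <- length(sigma_grid); nd <- length(delta_grid)

  # log-likelihood cube accumulated level by level, vectorized over (mu, sigma)
  ll <- array(0, dim = c(nm, ns, nd))
  for (r in seq_len(nrow(counts))) {
    x <- counts$delay_s[r]; k <- counts$detected[r]; n <- counts$used[r]
    Phi <- pnorm(outer(x - mu_grid, 1 / sigma_grid, `*`))
    for (j in seq_len(nd)) {
      p <- delta_grid[j] / 2 + (1 - delta_grid[j]) * Phi
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll[, , j] <- ll[, , j] + k * log(p) + (n - k) * log1p(-p)
    }
  }
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  joint <- apply(post, c(1, 2), sum)             # delta marginalized out

  mi <- arrayInd(which.max(joint), dim(joint))
  at_edge <- mi[1] %in% c(1L, nm) || mi[2] %in% c(1L, ns)

  if (delta_for_threshold == "mid") {
    delta_bar <- matrix(0.03, nm, ns)
  } else {
    # posterior-mean delta per (mu, sigma) cell
    num <- matrix(0, nm, ns)
    for (j in seq_len(nd)) num <- num + delta_grid[j] * post[, , j]
    delta_bar <- ifelse(joint > 0, num / joint, mean(delta_grid))
  }
  # invert the mixture at 0.7 per cell; guarded for unreachable targets
  target <- (0.7 - delta_bar / 2) / (1 - delta_bar)
  target <- pmin(pmax(target, 1e-9), 1 - 1e-9)
  thr <- outer(mu_grid, rep(1, ns)) +
    outer(rep(1, nm), sigma_grid) * qnorm(target)
  threshold70_s <- sum(joint * thr)

  structure(list(mu_grid = mu_grid, sigma_grid = sigma_grid,
                 delta_grid = delta_grid, joint = joint,
                 mode = list(mu = mu_grid[mi[1]], sigma = sigma_grid[mi[2]],
                             at_edge = at_edge),
                 threshold70_s = threshold70_s,
                 threshold_matrix = thr),
            class = "psychometric_posterior")
}

#' Posterior-averaged 70% detection threshold
#'
#' For every (mu, sigma) grid point the delay solving p(x) = 0.7 under the
#' delta-averaged mixture curve is interpolated, then averaged over the joint
#' posterior.
#'
#' @param posterior `psychometric_posterior`.
#' @return threshold (s).
#' @export
threshold70 <- function(posterior) posterior$threshold70_s

#' Central posterior interval of the 70% threshold
#'
#' @param posterior `psychometric_posterior`.
#' @param level central probability mass (default 0.95).
#' @return numeric c(lower, upper) in seconds (posterior-weighted quantiles
#'   of the per-cell threshold).
#' @export
threshold70_interval <- function(posterior, level = 0.95) {
  thr <- as.vector(posterior$threshold_matrix)
  w <- as.vector(posterior$joint)
  ord <- order(thr)
  cw <- cumsum(w[ord])
  a <- (1 - level) / 2
  c(lower = thr[ord][which(cw >= a)[1]],
    upper = thr[ord][which(cw >= 1 - a)[1]])
}

#' @export
print.psychometric_posterior <- function(x, ...) {
  cat(sprintf(
    "<psychometric_posterior> mode mu = %.3f s, sigma = %.3f s%s; 70%% threshold = %.3f s\n",
    x$mode$mu, x$mode$sigma, if (x$mode$at_edge) " (grid edge)" else "",
    x$threshold70_s))
  invisible(x)
}
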