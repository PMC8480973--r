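#' Trial record container
#'
#' The universal exchange object: synchronously sampled channels of body
#' angle, torque, imposed delay, vestibular stimulus, EMG envelope and button
#' state, plus metadata. Channels not produced by a given stage default to
#' zeros so every record carries the full schema.
#'
#' @param time_s sample times (s), uniformly spaced from 0.
#' @param theta_deg body angle (deg, positive anterior).
#' @param theta_dot_dps angular velocity (deg/s).
#' @param torque_nm ankle torque (N.m).
#' @param delay_ms imposed delay channel (ms).
#' @param evs_ma vestibular stimulus current (mA).
#' @param emg_au EMG envelope (arbitrary units or %EMG after scaling).
#' @param button binary button state.
#' @param fs sample rate (Hz).
#' @param meta named list of metadata (seeds, configs, ground truth).
#' @return object of class `trial_record` (a data.frame with attributes
#'   `fs` and `meta`).
#' @export
trial_record <- function(time_s, theta_deg = NULL, theta_dot_dps = NULL,
                         torque_nm = NULL, delay_ms = NULL, evs_ma = NULL,
                         emg_au = NULL, button = NULL, fs, meta = list()) {
  n <- length(time_s)
  fill <- function(x) if (is.null(x)) numeric(n) else check_finite(x, "channel")
  cols <- list(time_s = time_s,
               theta_deg = fill(theta_deg),
               theta_dot_dps = fill(theta_dot_dps),
               torque_nm = fill(torque_nm),
               delay_ms = fill(delay_ms),
               evs_ma = fill(evs_ma),
               emg_au = fill(emg_au),
               button = as.integer(fill(button)))
  lens <- vapply(cols, length, integer(1))
  if (any(lens != n))
    stopf("channel length mismatch: %s",
          paste(names(cols)[lens != n], collapse = ", "))
  df <- as.data.frame(cols)
  attr(df, "fs") <- fs
  attr(df, "meta") <- meta
  class(df) <- c("trial_record", "data.frame")
  df
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %d samples @ %g Hz (%.1f s)\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")))
  invisible(x)
}

trial_fs <- function(trial) attr(trial, "fs")

TRIAL_COLUMNS <- c("time_s", "theta_deg", "theta_dot_dps", "torque_nm",
                   "delay_ms", "evs_ma", "emg_au", "button")

#' Write / read a trial record (CSV + JSON sidecar)
#'
#' The record is written as plain CSV with the canonical column set; sample
#' rate and metadata (including any ground-truth sidecar) go to `<path>.json`.
#' Reading validates the schema: all columns present, time monotone and
#' consistent with the sidecar sample rate.
#'
#' @param trial `trial_record`.
#' @param path CSV file path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns the
#'   reconstructed `trial_record`.
#' @export
write_trial <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  side <- list(fs = trial_fs(trial), n = nrow(trial), meta = attr(trial, "meta"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing))
    stopf("trial file %s missing column(s): %s", path,
          paste(missing, collapse = ", "))
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stopf("missing sidecar %s", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stopf("non-monotone time in %s", path)
  if (abs(stats::median(dt) - 1 / side$fs) > 0.001 / side$fs)
    stopf("sample-rate mismatch in %s: sidecar fs=%g, data dt=%g",
          path, side$fs, stats::median(dt))
  trial_record(df$time_s, df$theta_deg, df$theta_dot_dps, df$torque_nm,
               df$delay_ms, df$evs_ma, df$emg_au, df$button,
               fs = side$fs, meta = if (is.null(side$meta)) list() else side$meta)
}
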