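SESSION_TAGS <- c("exp1", "training", "exp2-vest", "exp2-percept", "exp3")

#' Instantiate a session design
#'
#' Builds the per-trial delay schedules replicating one experiment's session
#' structure for a single participant:
#' \describe{
#'   \item{exp1}{six 60 s trials at fixed imposed delays 20, 100, 200, 300,
#'     400, 500 ms (ascending order).}
#'   \item{training}{ten 600 s trials at the 400 ms delay (two 10 min trials
#'     per day over five days).}
#'   \item{exp2-vest}{four 20 s trials per delay for each of the six delays
#'     (24 trials, 80 s of data per condition).}
#'   \item{exp2-percept}{`n_trials` (default 10) trials; each holds 14 delay
#'     periods of 8 s (two per level of 50-350 ms) in random order, baseline
#'     20 ms between periods, inter-transition interval uniform 7-10 s. Ten
#'     trials give 20 periods per level (5% resolution).}
#'   \item{exp3}{six trials of 14 periods each, all 200 ms for 8 s, interval
#'     uniform 8-9 s; 84 periods per participant.}
#' }
#'
#' @param tag experiment tag, one of `exp1`, `training`, `exp2-vest`,
#'   `exp2-percept`, `exp3`.
#' @param seed RNG seed for the random orderings and intervals.
#' @param participants number of participant designs to instantiate; when
#'   greater than one, a list of designs (class `session_set`) is returned
#'   with independent child seeds.
#' @param n_trials overrides the per-participant trial count where the design
#'   allows it (exp2-percept).
#' @param percept_levels_ms delay levels for perceptual testing (ms).
#' @return object of class `session_design` with fields `experiment`,
#'   `baseline_delay_ms` and `trials` (list of `list(duration_s, periods)`
#'   where `periods` is a data.frame onset_s/delay_ms/duration_s); or a
#'   `session_set` list of such designs.
#' @export
make_session <- function(tag, seed = NULL, participants = 1L, n_trials = NULL,
                         percept_levels_ms = c(50, 100, 150, 200, 250, 300, 350)) {
  if (!tag %in% SESSION_TAGS)
    stopf("unknown experiment tag '%s'; valid tags: %s", tag,
          paste(SESSION_TAGS, collapse = ", "))
  if (participants > 1L) {
    out <- lapply(seq_len(participants), function(p)
      make_session(tag, child_seed(seed, p), 1L, n_trials, percept_levels_ms))
    class(out) <- "session_set"
    return(out)
  }

  fixed_trial <- function(delay, dur)
    list(duration_s = dur,
         periods = data.frame(onset_s = 0, delay_ms = delay, duration_s = dur))

  transition_trial <- function(delays, iti_lo, iti_hi, period_s = 8,
                               lead_in_s = 8) {
    onsets <- numeric(length(delays))
    t <- lead_in_s
    for (i in seq_along(delays)) {
      onsets[i] <- t
      t <- t + period_s + runif(1, iti_lo, iti_hi)
    }
    list(duration_s = ceiling(t),
         periods = data.frame(onset_s = onsets, delay_ms = delays,
                              duration_s = period_s))
  }

  trials <- with_seed(seed, switch(
    tag,
    "exp1" = lapply(c(20, 100, 200, 300, 400, 500), fixed_trial, dur = 60),
    "training" = lapply(rep(400, 10), fixed_trial, dur = 600),
    "exp2-vest" = {
      conds <- rep(c(20, 100, 200, 300, 400, 500), each = 4)
      lapply(conds, fixed_trial, dur = 20)
    },
    "exp2-percept" = {
      nt <- if (is.null(n_trials)) 10L else n_trials
      lapply(seq_len(nt), function(i)
        transition_trial(sample(rep(percept_levels_ms, 2)), 7, 10))
    },
    "exp3" = lapply(seq_len(6), function(i)
      transition_trial(rep(200, 14), 8, 9))
  ))
  structure(list(experiment = tag, baseline_delay_ms = 20, seed = seed,
                 trials = trials),
            class = "session_design")
}

#' Count delay periods in a design
#'
#' @param design `session_design` or `session_set`.
#' @return total number of delay periods.
#' @export
n_periods <- function(design) {
  if (inherits(design, "session_set"))
    return(sum(vapply(design, n_periods, numeric(1))))
  sum(vapply(design$trials, function(tr) nrow(tr$periods), numeric(1)))
}

# per-trial piecewise-constant delay schedule (data.frame time_s/delay_ms)
trial_schedule <- function(trial_design, baseline_delay_ms = 20) {
  p <- trial_design$periods
  if (nrow(p) == 1L && p$onset_s[1] == 0 &&
      p$duration_s[1] >= trial_design$duration_s)
    return(data.frame(time_s = 0, delay_ms = p$delay_ms[1]))
  times <- c(0, as.vector(rbind(p$onset_s, p$onset_s + p$duration_s)))
  delays <- c(baseline_delay_ms,
              as.vector(rbind(p$delay_ms, rep(baseline_delay_ms, nrow(p)))))
  data.frame(time_s = times, delay_ms = delays)
}

#' Synthesize a complete experiment dataset
#'
#' End-to-end composition of plant, controller, stimulus, EMG and button
#' generators for any session design. Every stochastic step is seeded from
#' `seed`; the generating parameters are returned as a ground-truth sidecar
#' so recovery tests can read only the data and compare against it.
#'
#' During delay periods the vestibular coupling gain is attenuated: for
#' transient designs it decays exponentially (time constant
#' `atten_tau_s`, floor `atten_floor`) from period onset and recovers after
#' the period; for fixed-delay designs a per-delay gain map is applied
#' (imposed delays >= 200 ms attenuate the coupling).
#'
#' @param tag experiment tag (see [make_session()]).
#' @param seed master seed.
#' @param params `pendulum_params` (its `fs` sets the record rate; 200 Hz
#'   keeps desk-scale runtimes, 2000 Hz matches the robot).
#' @param limits `limit_config`.
#' @param ctrl `controller_params`.
#' @param truth `percept_truth` for button generation.
#' @param coupling `vestibular_coupling` template (its gain_schedule is
#'   replaced by the design-driven schedule).
#' @param evs_rms_ma stimulus RMS (mA).
#' @param atten_tau_s coupling attenuation time constant during transient
#'   delay periods (s).
#' @param atten_floor asymptotic coupling gain during a delay period.
#' @param delay_gain_map named vector mapping fixed imposed delays (ms) to
#'   coupling gains.
#' @param emg_tonic,emg_noise_std EMG envelope generator settings.
#' @param n_trials optional trial-count override (passed to make_session).
#' @return list with `trials` (list of `trial_record`), `design`
#'   (`session_design`) and `truth` (ground-truth sidecar list).
#' @export
synthesize_experiment <- function(tag, seed = 1L,
                                  params = pendulum_params(sample_rate_hz = 200),
                                  limits = limit_config(params),
                                  ctrl = controller_params(),
                                  truth = percept_truth(),
                                  coupling = vestibular_coupling(amplitude = 0.15),
                                  evs_rms_ma = 1.38,
                                  atten_tau_s = 1.5, atten_floor = 0.1,
                                  delay_gain_map = c("20" = 1, "100" = 0.9,
                                                     "200" = 0.5, "300" = 0.25,
                                                     "400" = 0.15, "500" = 0.1),
                                  emg_tonic = 10, emg_noise_std = 1.5,
                                  n_trials = NULL) {
  design <- make_session(tag, child_seed(seed, 1), n_trials = n_trials)
  fs <- params$fs
  percept <- tag %in% c("exp2-percept", "exp3")
  transient <- percept        # transient designs have within-trial transitions

  gain_fun <- function(periods) {
    if (transient) {
      function(t) {
        g <- rep(1, length(t))
        for (i in seq_len(nrow(periods))) {
          on <- periods$onset_s[i]; off <- on + periods$duration_s[i]
          inside <- t >= on & t < off
          # amplitude = sqrt of the scheduled power decay, so coupling POWER
          # (hence coherence, in the weak-coupling regime) has time constant
          # atten_tau_s
          g[inside] <- sqrt(atten_floor + (1 - atten_floor) *
                              exp(-(t[inside] - on) / atten_tau_s))
        }
        pmin(pmax(g, 0), 1)
      }
    } else {
      d <- as.character(periods$delay_ms[1])
      gd <- if (d %in% names(delay_gain_map)) delay_gain_map[[d]] else 1
      function(t) rep(gd, length(t))
    }
  }

  trials <- vector("list", length(design$trials))
  for (k in seq_along(design$trials)) {
    tr <- design$trials[[k]]
    sk <- child_seed(seed, 100 + k)
    res <- run_closed_loop(params, limits, ctrl,
                           trial_schedule(tr, design$baseline_delay_ms),
                           tr$duration_s, seed = sk)
    trial <- res$trial
    evs <- generate_evs(evs_config(tr$duration_s, fs = fs,
                                   target_rms_ma = evs_rms_ma,
                                   seed = child_seed(seed, 200 + k)))
    cp <- coupling
    cp$gain_schedule <- gain_fun(tr$periods)
    emg <- generate_emg(trial, evs, cp, tonic = emg_tonic,
                        noise_std = emg_noise_std,
                        seed = child_seed(seed, 300 + k))
    button <- if (percept)
      generate_button(tr$periods, tr$duration_s, truth, fs = fs,
                      seed = child_seed(seed, 400 + k))
    else integer(nrow(trial))
    trials[[k]] <- trial_record(
      trial$time_s, trial$theta_deg, trial$theta_dot_dps, trial$torque_nm,
      trial$delay_ms, evs, emg, button, fs = fs,
      meta = c(attr(trial, "meta"),
               list(experiment = tag, trial_index = k,
                    limit_crossings = res$limit_crossings)))
  }
  truth_sidecar <- list(
    experiment = tag, seed = seed, fs = fs,
    mu_s = truth$mu_s, sigma_s = truth$sigma_s, delta = truth$delta,
    evs_rms_ma = evs_rms_ma, atten_tau_s = atten_tau_s,
    atten_floor = atten_floor,
    coupling_short_ms = coupling$short_ms,
    coupling_medium_ms = coupling$medium_ms,
    delay_gain_map = as.list(delay_gain_map))
  ds_log("synthesize", experiment = tag, trials = length(trials), fs = fs)
  list(trials = trials, design = design, truth = truth_sidecar)
}
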