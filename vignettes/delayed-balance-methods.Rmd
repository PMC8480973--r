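---
title: "Methods: simulating and analysing standing balance under imposed sensorimotor delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing standing balance under imposed sensorimotor delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaystand)
```

# The problem

Standing upright is a control problem with dead time: proprioceptive,
vestibular and visual feedback of whole-body motion reaches the controller
100-160 ms after the fact. Robotic balance simulators can enlarge this delay
artificially — buffering the ankle torque a person produces and applying it
to the simulated body 20-500 ms later — which destabilizes stance, attenuates
vestibular-evoked muscle responses, and makes self-generated sway feel
externally imposed. `delaystand` re-implements the desk-scale computational
machinery of such an experiment: the plant simulation, sway and
vestibulomotor analyses, and psychometric fitting, together with a synthetic
participant so that every stage is testable without hardware or humans.

# The plant

The body is a linearized single-link inverted pendulum about the ankles,

$$ I\,\ddot\theta - m_m g L\,\theta = T,$$

with effective moving mass $m_m = 0.971\,m$ (the feet do not ride on the
backboard), $I = m_m L^2$, and $\theta > 0$ an anterior lean. The update is
the exact zero-order-hold discretization (matrix exponential of the 2-state
system), so piecewise-constant torque trajectories match the analytic
solution of the ODE to machine precision — this is tested against an
independently coded scalar cosh/sinh propagation, not against the same
matrix code.

Virtual limits at +6 deg (anterior) and -3 deg (posterior) emulate the
physical bounds of sway. Beyond a limit a passive supportive torque ramps
linearly from zero to a threshold over 1 deg and then holds the body at the
secondary limit (7/-4 deg). The secondary limit itself is enforced two
ways: the ramp slope keeps steepening past it (`barrier_gain`, default 20x),
and the simulator applies a hard kinematic stop (projection with inelastic
contact) — the robot "cannot rotate further regardless of ankle torques",
so confinement is a constraint, not a finite spring, while the ramp and the
beyond-limit damping provide the smooth attenuation on approach. Two quantities the source description leaves
open are exposed as parameters with documented defaults:

* `support_torque_nm` — "equivalent to the body load" is read as the
  gravitational toppling torque at the secondary limit,
  $m_m g L \sin(\text{limit} + 1^\circ)$, the torque the support must cancel
  to hold the body passively at that angle.
* `damping_nms` — only said to "smoothly attenuate motion"; the default is
  the critical-damping scale $2\sqrt{I\,m_m g L}$, applied only beyond the
  limits. The delay-sweep behaviour reported below is insensitive to this
  constant over at least an order of magnitude (verified during design).

Internally all angles are radians; every I/O surface (records, configs,
limits) is degrees, matching how such experiments are reported. Sub-sample
delays round to the nearest sample; at the native 2000 Hz that is 0.25 ms
resolution, far below any delay of interest. A decimated 200 Hz mode (the
test default) recomputes the zero-order hold for the coarser step, so it is
exact at that rate too, and reproduces the same qualitative closed-loop
behaviour.

# The stand-in controller

No human controller is specified by the source experiment, so the package
ships the minimal stand-in consistent with the feedback-model literature: a
proportional-derivative law on the state sensed through an intrinsic
sensorimotor delay (default 120 ms), plus band-limited Gaussian torque noise
(default 5 Hz bandwidth). Intermittent or predictive controllers are out of
scope by design.

The default gains (`kp` = 690 N·m/rad, `kd` = 120 N·m·s/rad) and noise
level (1 N·m) were fixed once, by calibration at the baseline condition
before the analysis tests were frozen, to satisfy three stated desiderata
simultaneously:

* `kp` must exceed the gravitational stiffness $m_m g L \approx 679$ N·m/rad
  (necessary for stability at all);
* baseline (20 ms imposed) sway velocity variance lands near 0.07 (deg/s)²,
  the order of magnitude reported for quiet robot-standing;
* across imposed delays 20-400 ms the group-mean windowed sway-velocity
  variance is non-decreasing and the limits are crossed at every delay
  $\ge$ 200 ms.

The third point deserves honesty: a *fixed-gain* delayed PD controller has a
hard stability margin. With stiff, human-plausible gains the margin sits
near 150-220 ms of imposed delay, and the windowed variance then *peaks* at
the first super-critical delay and falls again — the sustained near-marginal
oscillation outscores the brief launch transients at larger delays. Humans
do not behave this way (they keep producing vigorous corrective sway well
past the critical delay). The chosen low-gain regime (margin ≈ 47 ms,
`stability_margin()`) instead puts every delay ≥ 100 ms in the same
launch-and-bounce regime, whose in-limit variance grows with the instability
growth rate, restoring the monotone pattern. The cost is that limit
crossings already appear at 100 ms, where real participants almost never
crossed; we judged the monotone variance pattern (the experiment's primary
behavioural signature) the more important feature to reproduce and note
this divergence as a known limitation.

# Synthetic signals

**Vestibular stimulus.** Seeded Gaussian white noise, low-pass filtered to
0-25 Hz and rescaled to an exact RMS (1.38 mA by default; the fixed-delay
sessions used 1.47-1.61 mA). Because no IIR filter-design package is
available in the target environment, all "zero-phase Butterworth" filtering
in the package applies the squared magnitude response of the half-order
filter via FFT with reflection padding — *exactly* the magnitude a
forward-backward (filtfilt) cascade of overall order $n$ realizes, and
zero-phase by construction. The alternative reading ("order n applied
twice") is a config switch (`squared = FALSE`).

**EMG envelope.** The vestibular-evoked muscle response is injected as a
biphasic impulse response: two opposite-signed Gaussian lobes peaking at 60
and 100 ms (widths 15/25 ms), convolved causally with the stimulus, on top
of a tonic level, optional torque-proportional drive, and seeded noise, with
rectification at zero. A time-varying `gain_schedule` in [0, 1] scales the
coupling. During delay periods the schedule applies
$\sqrt{f + (1-f)e^{-t/\tau}}$ to the *amplitude*, so the coupling **power**
— and therefore coherence, in the weak-coupling regime — decays
exponentially with the stated time constant $\tau$ (default 1.5 s, floor
$f = 0.1$). The attenuation is imposed, not emergent: the generator
reproduces the phenomenon, not its mechanism.

**Button presses.** Each delay period is detected with probability
$\delta/2 + (1-\delta)\Phi((x-\mu)/\sigma)$ from a ground-truth observer
(default $\mu = 0.15$ s, $\sigma = 0.05$ s, $\delta = 0.02$). Detected
periods get a press at onset plus a shifted-lognormal latency (floor 0.5 s,
median ≈ 2.7 s, calibrated to the observed 2-5 s detection times);
latencies beyond the 8 s period truncate to the period end and still count.
False presses occur between periods at 0.1/min to exercise the exclusion
rule.

**Session designs** replicate the experiments' structure exactly: the
six-delay 60 s sweep; ten 10-min 400 ms training trials; four 20 s trials
per delay for vestibular testing; ten perceptual trials of fourteen 8 s
periods (two per level, inter-transition interval uniform 7-10 s, giving 20
periods per level); and six transient-200 ms trials of fourteen periods
(interval 8-9 s, 84 periods per participant, 588 across seven).

# Analyses

**Sway.** Windowed measures follow the stated rules literally:
non-overlapping 2 s windows packed from the start of each maximal
continuous in-limit run (an 11 s run yields five windows), per-window
unbiased sample variance of angular velocity averaged across windows, and
percent time in limits per 60 s interval. Velocity uses central finite
differences without smoothing (the velocity signal lives above 0.5 Hz, so
no detrending inside 2 s windows). A trace with no eligible window returns
an explicit NA sentinel with a zero count, never a silent zero. The sliding
2 s variance is centered with shrinking edge windows, so it begins rising
up to 1 s before an event — the same pre-onset rise the windowed
time-course displays around delay transitions.

**Exponential fits** $f(x) = a e^{-x/b} + c$ profile $(a, c)$ out by linear
least squares and search $b$ on a 60-point logarithmic grid spanning
[x-range/100, x-range × 10], refined by golden-section — deterministic, no
starting-value luck. Degenerate inputs (constant data, boundary time
constants, $|a| \approx 0$) are flagged unidentifiable rather than
reported. The landmarks $b$ (63.2% attenuation) and $3b$ (95%) are stored
on every fit.

**Fourier coupling.** EMG preprocessing is a 30 Hz zero-phase high-pass of
overall order 6 followed by full-wave rectification; envelopes are scaled
by the mean quiet-standing envelope within ±0.25 deg of the preferred
(median) posture. Spectra average disjoint, non-overlapping,
rectangular-windowed 2048-sample segments (~0.98 Hz resolution at 2000 Hz;
trailing partial segments are discarded; per-channel means removed).
Coherence $|P_{sr}|^2/(P_{ss}P_{rr})$ is compared against the
$1 - 0.05^{1/(L-1)}$ limit; gain $|P_{sr}|/P_{ss}$ carries a reliability
mask wherever coherence is sub-threshold. The cross-covariance is the
inverse transform of the averaged cross spectrum on lags
$(-n/2, n/2]/f_s$, positive lag = EMG lagging stimulus. Its 95% interval is
the analytic ±1.96 SD under independence,
$\mathrm{Var}\,\hat q = \sum_f P_{ss}P_{rr} / (L\,n^2)$ (the cited
framework's variance, re-derived since the source only references it), with
a phase-randomization bootstrap provided as a cross-check. Short- (50-70
ms) and medium-latency (100-120 ms) extrema are zeroed when sub-threshold;
the response amplitude is the difference of the possibly-zeroed peaks, so a
doubly sub-threshold response is zero and "absent". Pooling across
participants averages spectra weighted by segment count — identical to
concatenating the segments — and lowers the coherence limit monotonically.

**Wavelet coupling.** Forty complex Morlet wavelets span 0.5-25 Hz linearly
with cycle counts geometrically spaced 3-12. "Logarithmically spaced" was
the one genuinely ambiguous spacing rule; geometric spacing is validated by
reproducing the printed FWHM endpoints (168-2249 ms temporal, 0.39-5.25 Hz
spectral) — including the non-obvious fact that the temporal minimum falls
at an *interior* wavelet (~17.5 Hz), not at 25 Hz, exactly as the printed
168 ms requires. Wavelets are sampled over ±5σ, zero-mean to better than
1e-6 and unit energy. Transition segments (8 s before onset, 8 s delay, 8 s
after) are convolved via FFT with reflection padding; per-transition cross
and auto products (not per-transition coherences) are averaged; the first
and last 2 s of the map are trimmed for edge distortion; significance uses
$1 - \alpha^{1/(K-1)}$ with $K$ transitions and $\alpha = 0.01$ (the
stricter 99% limit used for the time-frequency maps; configurable). Band
means average coherence over 0.5-25 Hz, and gain only over significant
cells, with flagged gaps when none exist at a time point.

Wavelet estimates smear time by the envelope FWHM (up to 2.2 s at 0.5 Hz),
and coherence compresses its input ($C = S/(1+S)$), so attenuation
time-constant recovery is only unbiased in the weak-coupling (linear)
regime. The recovery benchmark therefore injects a weak coupling (band-mean
baseline coherence ≈ 0.06, comparable to pooled human maps) and pools ~300
transitions, mirroring the pooled analysis; at moderate coherence the
fitted constant inflates by 50-100% — a genuine property of the estimator,
documented rather than hidden.

**Psychometrics.** Periods are detected (press within), missed, or excluded
(button already held at onset); exclusions leave the denominator, and used
+ excluded = presented always. The lapse-mixture likelihood is binomial on
per-level counts over the exact printed grids ($\mu$ 0-0.5 step 0.005,
$\sigma$ 0.01-5 step 0.01, $\delta$ 0.01-0.05 step 0.01, uniform prior,
log-space). $\delta$ is marginalized before the $(\mu,\sigma)$ mode is
taken. For the 70% threshold the source is ambiguous about which $\delta$
enters the interpolation; the default uses the posterior-mean $\delta$ per
$(\mu,\sigma)$ cell, with a fixed mid-grid $\delta = 0.03$ switch. The
threshold is the posterior-weighted average of the per-cell interpolated
70% points; a central posterior interval is available for calibration
checks. Period-level (not trial-level) exclusion accounting was chosen to
match the "used trials" bookkeeping of the detection tables.

# What the synthetic world does and does not establish

The generator reproduces the *structure* of the experiments (designs,
counts, signal classes, coupling morphology, detection behaviour) and known
closed-form anchors, so green tests establish that the analysis code
computes what it claims on data of the right shape and scale. It does not
model spinal/muscular physiology, intermittent or adaptive human control,
learning across sessions (gain retuning emulates its end state only),
electrode or mechanical artifacts, or the mechanism of vestibular
attenuation. Group-level human quantities (absolute sway variances at large
delays, thresholds of 147-192 ms, decay constants) are calibration context,
not targets; tests that reference them check orderings and orders of
magnitude only.

# Numerical choices

* Unbiased (n−1) sample variance throughout; documented because the source
  is silent.
* Coherence at frequencies with zero autospectrum is flagged undefined, not
  0/0.
* Psychometric likelihoods are clamped to [1e-12, 1−1e-12] before logs;
  the posterior normalizes to 1 within 1e-12.
* The 70% target is guarded against unreachability ($1-\delta/2 < 0.7$
  cannot occur on the stated $\delta$ grid, but the inversion clamps
  anyway).
* Delay schedules are piecewise-constant from each breakpoint; a schedule
  not covering t = 0 is a configuration error, not a default.
* `fit_exponential` reports `identifiable = FALSE` when $|a|$ is numerically
  zero, data are constant, or $b$ lands on the search boundary.

# Known limitations

* The stand-in controller crosses the virtual limits at 100 ms imposed
  delay, earlier than humans did; see the controller section.
* Wavelet attenuation constants are only recoverable in the weak-coupling
  regime; moderate-coherence estimates are biased long.
* The cross-covariance confidence interval treats segments as independent;
  at low frequencies neighbouring wavelet samples are not, and the
  transition-count limit formula shares that caveat (noted, unresolved by
  the source).
* `retune_gains` is a coordinate grid search; it emulates the *outcome* of
  training, not its dynamics.
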