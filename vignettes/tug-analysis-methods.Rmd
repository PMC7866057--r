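---
title: "Methods: radar + insole analysis of the Timed Up and Go test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radar + insole analysis of the Timed Up and Go test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugkit)
```

The Timed Up and Go (TUG) test is a standard clinical mobility screen: the
subject rises from a chair, walks 3 m, turns 180 degrees, walks back and
sits down. `tugkit` analyses one TUG trial observed by two unobtrusive
sensors at once -- an ultra-wideband radar that reports the range to the
subject a few times per second, and a single instrumented insole that
reports anteroposterior acceleration and plantar force at ~100 Hz -- and
condenses the resulting gait parameters into a 0-100 risk-of-falling
(ROFA) score. This vignette documents the models, the tunable parameters,
the numerical choices, and what the bundled simulator does and does not
emulate.

## Radar-side model

### Velocity from range: constant-acceleration Kalman filter

Differentiating a noisy range trace amplifies noise exactly where the
decision thresholds live (low-speed regions), so gait velocity is
estimated with a discrete Kalman filter whose state is (position,
velocity, acceleration). The transition model is the standard
constant-acceleration one,

$$p_{k+1} = p_k + v_k T_s + \tfrac12 a_k T_s^2,\qquad
  v_{k+1} = v_k + a_k T_s,\qquad a_{k+1} = a_k,$$

with the measurement matrix selecting position only. Defaults: update
interval `ts_s` = 0.2 s, measurement-noise variance `r` = 0.04 m^2, and
process noise held constant at its initial value `q0_diag` =
diag(0.04, 0.01, 0.01). The filter is started at the first measurement
with zero velocity and acceleration and covariance Q0; the update uses
the Joseph form so the covariance stays symmetric positive semi-definite
over arbitrarily long runs. On noisy ramps this filter's velocity RMSE is
several times smaller than first-order finite differences, which is the
property the segmentation relies on.

### Activity segmentation

Six transition points split the trial into five phases. With D the
filtered range, `D_pos` the radar-to-chair distance (default 0.5 m),
`d_qs` the chair-to-standing distance (default 0.3 m) and a 3 m walkway:

* onset: the first sample whose filtered speed reaches
  `velocity_threshold_mps` (default 0.4 m/s, a literature walking-onset
  threshold). If the speed never gets there within
  `quasi_static_timeout_s` (30 s) the trace is declared quasi-static.
* T0: first point with D > `D_pos`, searched in a 3 s look-back window
  from the onset; T1: first point with D >= `D_pos` + `d_qs`. These
  bound sit-to-stand.
* T2: first point with D >= `D_pos` + 3 m; T3: last point of the
  contiguous run staying within `turn_tolerance_m` (0.1 m, one radar
  range cell) of that level. [T2, T3] is the turn; exact re-crossing of
  a threshold on discrete noisy data needs this tolerance.
* T4: first point after T3 with D back at or below `D_pos` + `d_qs`
  (end of walk-back).
* T5: first point after T4 with D within `sit_tolerance_m` (0.03 m) of
  `D_pos` -- the geometric mirror image of the T0 rule. A velocity-quiet
  rule (speed below threshold for a full onset window) is the fall-back
  when the chair range is never re-reached. We chose the position rule
  because a realistic stand-to-sit descends at ~0.3 m/s, already below
  the 0.4 m/s threshold, so a velocity rule fires almost immediately
  after T4 and cannot localize the end of sitting; the chair range can.

Every threshold comparison requires two consecutive qualifying samples
(reported at the first of the pair). This one-sample persistence rejects
single-sample noise spikes without adding measurable latency at 5 Hz.

Radar stride length is the absolute range displacement across a stride
interval (sign-free, so the same rule serves the walk back), evaluated by
cubic-spline interpolation because stride boundaries rarely coincide with
radar samples; stride speed is length over duration. When the two sensor
streams must share a clock, `resample_trace()` interpolates the radar
range with a cubic spline, but transition points are always located on
the original samples first.

## Insole-side model

### Preprocessing

The acceleration is z-scored (population SD, i.e. divide by the SD with
denominator N -- fixed once for reproducibility) and the total force (sum
of the selected FSR channels) is normalized by its maximum. Raw
acceleration is kept alongside: the stride-length estimators need the
amplitude information that z-scoring destroys, so segmentation uses the
normalized copy and estimation the raw copy. The normalized acceleration
is median-filtered (`median_window` = 5 samples, removing single-sample
impulses) and low-pass filtered with a zero-phase Butterworth
(`butterworth_order` = 2 applied forward-backward, cutoff
`butterworth_cutoff_hz` = 3 Hz, covering typical gait bandwidth while
preserving peak timing). The forward-backward pass is wrapped in
odd-reflection padding; without it the filter's edge transients corrupt
the first and last half second. A gentle order was chosen deliberately:
sharper filters ring around the brief heel-strike transients and the
ripple crosses zero near the quiet baseline, corrupting the locking
period.

### Stride detection: zero crossings, locking period, peak correction

The filtered signal crosses zero twice per gait cycle of the instrumented
foot (once up into the swing-acceleration pulse, once down after it), so
the mean inter-crossing interval -- the locking period, lockP -- is about
half the stride time. Detection then proceeds:

1. tile the record with windows of length lockP and take each window's
   maximum as a candidate peak;
2. re-center a lockP window on each candidate and move it to the local
   maximum, iterating to a fixed point and merging duplicates (only
   positive excursions qualify -- after z-scoring a stride pulse is
   above the trial mean);
3. for each peak compute PL and PR, the drops from the peak to the
   minima immediately before (toe-off) and after (heel-strike) within
   the centered window;
4. shape-similarity correction: discard candidates whose smaller flank
   drop is below `prominence_frac` (0.3) of the upper-decile flank drop
   -- this is what separates true stride pulses from noise bumps in
   quiet regions, in the spirit of correcting peaks by shape rather
   than by an absolute threshold (an optional absolute gate,
   `peak_threshold_frac`, exists but is off by default);
5. gap rule: scanning left to right, a peak closer than lockP to the
   previously retained peak is invalidated, and a retained peak whose
   gap to the next retained peak exceeds `max_stride_time_s` (2.5 s) is
   invalidated; the rule is iterated to a fixed point so that
   re-validating a validated set changes nothing.

The stride count is the number of valid peaks minus one, and stride i
spans valid peak i to peak i+1 (successive pulses delimit one stride).
Peak times are refined to sub-sample resolution with a three-point
parabola, which matters when comparing stride times across sensors at
1-sample tolerances.

The force channel validates the count: swing unloads (force below a low
level, 0.2 of maximum, bounded on both sides by the stance level, 0.6,
with hysteresis against chatter) are counted and compared with the number
of acceleration peaks. `force_stride_times()` additionally derives stride
times from force alone (intervals between interpolated swing-onset
edges, confirmed only if the force re-arms within 0.8 s so the final
stand-to-sit decline is not mistaken for a swing), which supports the
sensor-reduction question: do two FSRs carry the same stride-timing
information as the accelerometer?

Sit-to-stand and stand-to-sit are also visible in force: the first
sustained rise from the seated plateau to the first attainment of the
standing level (0.95 of maximum), and the final decline back to the
ending plateau. "Seated plateau" means a sustained low period of at
least 1 s, with noise blips shorter than 0.2 s closed over -- brief swing
unloads must not masquerade as sitting.

### Stride length

Three estimators, all per stride window on raw acceleration:

* mean-absolute: $SL = K_1 \left(\tfrac1N\sum|A_{y,i}|\right)^{1/3}$,
  with $K_1 = 0.98$;
* Weinberg (hip-bounce): $SL = K_2 (A_{y,\max} - A_{y,\min})^{1/4}$;
* Scarlett (normalized mean):
  $SL = K_3 \tfrac1N\sum \frac{A_{y,i} - A_{y,\min}}{A_{y,\max} - A_{y,\min}}$.

$K_2 = K$ and $K_3 = 2K$ are maintained as a linked constraint with the
single calibration coefficient $K$ (default 0.9763) obtained as the mean
ratio of estimated to reference distances (`calibrate_k()`); in a
radar+insole deployment the radar displacement plays the reference.
Whether the estimators should run per stride or per bout is a genuine
ambiguity; we compute them per stride, which is what a per-stride
deviation score needs.

## ROFA score

For each gait parameter k (default set: stride length, stride time,
cadence, stride speed; cadence is 60 x steps-per-stride / stride time in
steps per minute, with 2 steps per stride configurable for pathological
gait) the deviation ratio against a baseline is
$R_k = |(G_k - G_{kM})/\sigma_k|$ and the per-parameter score
$S_k = 100 - 10R_k$, clamped to [0, 100] (the formula goes negative past
ten SDs; the score is defined on 0-100, so clamping reconciles the two).
Baselines pool all strides of all reference trials with the sample SD
(n-1; baselines come from few trials); zero-variance parameters are
excluded with a warning rather than dividing by zero. Scores are computed
per stride and averaged per parameter, then combined with convex weights
(equal by default) into the composite TUG score; scoring the trial-mean
parameter instead is available behind `aggregate = "trial_mean"`.
Bands: below 25 very high risk, then high, medium, low at 25/50/75, and
exactly 100 very low -- the printed integer ranges are implemented as
half-open real intervals so a continuous score between 24 and 25 still
lands in a band.

## Statistical comparison

Insole and radar stride lengths are compared with a paired two-sided
Wilcoxon signed-rank test: zero differences discarded (the classical
default), tied absolute differences mid-ranked, the exact null
distribution enumerated over all sign assignments for up to 15 non-zero
pairs, and the normal approximation with continuity and tie correction
above that. RMSE accompanies the p-value. The 0.05 level is reported,
never used to gate computation.

## The simulator and what passing tests mean

`simulate_tug()` generates the paired streams with ground truth. Radar:
a seated plateau at `D_pos` - 0.1 m (the torso rests against the
backrest behind the chair reference; without this set-back, seated
jitter would sit exactly on the T0 threshold), a quarter-sine
sit-to-stand rise (brisk start, easing into standing, 1 s), stride-wise
advance with +-8% intra-stride speed modulation, a turn plateau with a
small overshoot oscillation, the mirrored return and a quarter-cosine
stand-to-sit descent (easing out of standing, dropping onto the chair,
1 s). Walk-forward stride count is round((3 - d_qs)/stride length) --
2.7 m of forward travel after standing up, 0.04 m of overshoot at the
turn -- with per-stride lengths rescaled to sum to the travelled
distance. The turn is one full gait cycle at twice the stride time,
i.e. half the straight-line speed. Insole: one raised-cosine
acceleration pulse per stride boundary, flanked by a toe-off minimum
before and a deeper heel-strike minimum after (so PL and PR differ
generically), pulse amplitude following the fourth-power stride-length
relation (so the hip-bounce model holds by construction and calibration
is meaningful); force channels share a common stance/swing envelope with
seated plateaus at both ends. Defaults describe a healthy adult at
comfortable pace: 1.3 +- 0.05 m strides of 1.1 +- 0.05 s, 5 Hz radar
with 0.02 m range jitter, 100 Hz insole with accelerometer noise of a
few percent of the pulse amplitude.

What the simulator does **not** emulate: radar multipath and body-sway
micro-Doppler, multi-person scenes, asymmetric or pathological gait
(freezing, festination), inter-channel FSR timing differences (all
channels share one envelope, which is why channel subsets agree so
well), soft-tissue artefacts, and drift or saturation in either sensor.
Passing the recovery suites therefore shows that the algorithms invert
the stated signal model at realistic noise levels -- it does not certify
performance on clinical recordings.

Test problem sizes were chosen to exercise the chain densely while
staying quick: 100 simulated trials per segmentation battery (noise-free
and at 0.05 m radar / 15%-of-amplitude accelerometer noise), 50 trials
for the sensor-reduction comparison, 10+10 trials for calibration
transfer, and 100 seeds for the Kalman-versus-finite-difference
property.

## Known limitations

* The T4/T5 rules are choices (the turn-end and sit-end geometry), made
  symmetric to T1/T0; other conventions shift those two points by a few
  tenths of a second.
* The locking-period detector assumes one dominant acceleration pulse
  per gait cycle of the instrumented foot. Gait with strong contralateral
  signatures or shuffling would need the optional absolute threshold or
  a smaller `prominence_frac`.
* K calibration transfers a constant; it cannot correct the shape
  mismatch of an estimator whose functional form does not fit the
  wearer, which is why the three estimators can disagree systematically
  while each remains internally consistent.
* Band cut-offs of the ROFA score are conventions, not clinically
  validated thresholds.
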