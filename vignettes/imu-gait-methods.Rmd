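---
title: "Methods: IMU joint angles, stride length, and the synthetic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU joint angles, stride length, and the synthetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

This vignette documents the models implemented in imugait, the parameter
choices that matter, the numerical decisions, and — since all quantitative
claims rest on a synthetic signal generator — exactly what that generator
does and does not emulate.

## Conventions

All file interfaces use the sensors' native units: acceleration in G,
angular velocity in deg/s, angles in deg; SI conversions (g = 9.80665 m/s²)
happen inside the integration kernels. The canonical segment frame is
x anterior, y medio-lateral, z longitudinal pointing down the segment when
standing; the foot sensor uses x anterior along the foot and z dorsal.
A `placement_config()` (signed, right-handed axis permutations per segment)
maps whatever the physical mounting is onto these frames at ingest. Hip and
knee flexion and ankle dorsiflexion are positive. Motion is treated as
strictly sagittal-plane: `wy` is the only gyro channel the estimators use,
and no 3-D orientation (quaternion/magnetometer) machinery is involved.

Wireless sensors time-stamp samples with their own clocks;
`regularize_timestamps()` linearly interpolates every channel onto the
uniform nominal grid so that downstream filters can treat the sampling
interval as an exact constant. Gaps exceeding five nominal intervals are an
error rather than something to interpolate over.

## Joint-angle estimation

The gyro branch integrates the difference of the two segments' pitch rates
(cumulative trapezoid; second-order accurate at no cost) and anchors it at
the accelerometer tilt difference averaged over the first six samples — so
a trial should begin with the subject briefly still. The accelerometer
branch low-passes each acceleration channel with a causal 2nd-order
Butterworth at 0.5 Hz and converts the surviving (mostly gravitational)
vector to a tilt angle with a two-argument arctangent, which keeps standing
and inverted segments distinct. The filter is causal because the method is
meant to be usable online; its start-up state is initialized at the DC
steady state of the first sample, so a resting start produces no transient.

The error-state Kalman filter estimates the drift of the integrated angle.
Its state is the angle error and the per-sample bias increment; the same
process disturbance enters both state rows, so the process covariance is
the rank-one matrix `q_w * [[1,1],[1,1]]` (a diagonal alternative sits
behind `rank_one_q = FALSE`). The measurement is the discrepancy `dy`
between the two branches, the update is the standard scalar-measurement
correction in Joseph form (symmetry and positive semi-definiteness are
preserved; `r_v = Inf` gives exactly zero gain, i.e. pure integration), and
the corrected angle is `theta_hat = theta_gyro - d_theta_hat`. The bias
estimate is deliberately not fed back into the integrator — the corrected
angle is reconstructed, the raw integral left untouched — and `warm_start`
lets a session carry the bias increment estimate across trials.

**Forming the discrepancy.** A naive `dy = theta_gyro - theta_acc` contains
the full gait oscillation, because the low-pass removes it from the
accelerometer angle but not from the gyro angle: at a typical 0.8–0.9 Hz
stride frequency and tens of degrees of joint excursion, `dy` would
oscillate with an amplitude comparable to the joint excursion itself. Any
filter gain small enough to ignore that oscillation is then too slow to
track realistic bias drift, and any gain fast enough to track drift leaks
the oscillation into the correction. imugait therefore makes the two
branches symmetric: each segment's gyro-integrated tilt is propagated into
a predicted gravity direction (sin/cos pair), that pair is passed through
the *identical* low-pass + arctangent composition as the measured
acceleration, and `dy` is the difference of the results. The oscillatory
component then cancels almost exactly — in the noise-free limit `dy` is
identically zero and the filter leaves the exact gyro integral untouched —
while slow drift passes through the low-pass unchanged and remains fully
observable. This is the package's own design choice for realizing the
block diagram; it is what makes sub-0.2-degree noise-free self-consistency
and multi-degree-per-minute drift rejection achievable simultaneously.

**Filter parameters.** There are no canonical values for the Kalman
noise parameters of this kind of system, so imugait's
defaults are its own documented, overridable choice: `q_w = 1e-6` deg²,
`r_v = 1` deg², `P0 = diag(1, 0.01)` at 100 Hz. They were fixed by a grid
evaluation on the generator's default conditions, balancing three
pressures: smaller `q_w/r_v` slows drift tracking (a 1 deg/s injected bias
must stay bounded within a few degrees), larger values leak residual
oscillation and accelerometer disturbance into the correction. Anywhere in
roughly `q_w` 1e-7–1e-5 behaves similarly; the acceptance suite pins the
chosen point.

## Stride-length estimation

Movement detection works on the per-sample sum over the three accelerometer
axes of the absolute deviation from the resting gravity baseline. The raw
three-axis sum would sit near 1 G at rest, which would make the printed
0.15 G threshold meaningless, so the per-axis rest median is subtracted:
first estimated from the initial 0.5 s (trials start at rest) and then
re-estimated from all detected rest samples in a second pass. Onset is the
first of 3 consecutive supra-threshold samples; the end rule scans forward
windows of 10 samples for at least 3 sub-threshold samples and places the
offset at the first sub-threshold sample of the first qualifying window —
the earliest instant consistent with the rule, which is otherwise agnostic
about placement. A trailing movement with no detected end is kept but
flagged `end_not_detected`, and downstream summaries drop it, mirroring the
practice of discarding strides after a misdetection.

Within an interval, foot pitch comes from gyro integration seeded by
`foot_initial_tilt()` (six arcsin(a_x) samples immediately before onset;
values beyond ±1 G are clamped and flagged as movement contamination). The
projection `a_x cos θ − a_z sin θ` recovers the world-horizontal
acceleration with gravity cancelling identically in the geometry, so no
separate gravity subtraction is needed. Velocity integrates from zero —
valid because integration starts in the stationary state — and the linear
zero-velocity correction `v_c(t) = v(t) − (t/T) v(T)` removes exactly the
drift a constant acceleration error produces (a constant error integrates
to a linear velocity ramp), leaving the corrected velocity exactly zero at
both ends. The lateral axis has no tilt reference, so `v_y` is built
symmetrically from the baseline-removed y acceleration with the same linear
correction — the only self-consistent reading of the misalignment
correction — and the stride length is the Euclidean norm of the two
displacements, making it insensitive to sensor yaw within the tested ±20°.
Each detected movement interval of one foot is one stride
(foot-to-same-foot).

## The synthetic generator

`simulate_walk()` emulates the study conditions the method was designed
for: level walking at a self-regulated speed, sensors on seven segments,
100 Hz. Kinematics are built from smooth periodic waveforms — hip and knee
curves are ≤ 4-harmonic approximations shaped like common normative gait
curves and linearly rescaled to the requested ranges (defaults: hip −10° to
+30°, knee 0° to 60°); the foot trajectory is a minimum-jerk-style
displacement pulse of exactly `stride_length_m` (default 1.4 m, cadence 110
steps/min, i.e. a normal-speed walk) with a sin² elevation bump (default
8 cm) and a compactly supported pitch excursion, all identically zero
during the foot-flat dwell. The dwell occupies `stance_fraction − 0.25` of
the cycle, so the stationary-state premise of the detector holds *exactly*
in the ground truth. A 1 s quiet-standing lead-in and a 1.5 s smoothstep
speed ramp give the estimators the resting start they assume; the first
stride is therefore slower than the rest, which is why it is flagged and
excluded from summaries. Ankle truth is derived as foot pitch minus shank
tilt, so all three joints are mutually consistent with the streams.

Sensor outputs are analytic: gyros report the segment pitch rate plus a
per-trial constant bias (drawn N(0, 0.3²) deg/s), a bias random walk
(0.02 deg/s per √s), and white noise (0.5 deg/s); accelerometers report the
specific force of the actual sensor point — gravity plus the linear
acceleration of a point at the attachment radius along the segment chain —
projected into the segment frame, plus white noise (0.02 G). These noise
magnitudes are documented configuration, chosen once as representative of
small MEMS sensors with the offset-drift problem the filter exists to fix;
they are not claims about any particular device. `accel_motion = FALSE` is
a diagnostic mode in which accelerometers see gravity only; the noise-free
self-consistency checks of the joint pipeline use it, because with movement
acceleration present the accelerometer angle is biased at the degree level
and no drift-correcting filter can (or should) undo that.

`simulate_pendulum()` emulates a two-bar rig swung from a fixed pivot at
90 BPM (one metronome beat per half-cycle, 0.75 Hz): the thigh bar is a
sinusoid whose total excursion is drawn per trial within the requested
range (30–40, 50–60, or 70–80 deg for the slow/normal/fast conditions), and
the shank responds passively with a coupling gain of 1.8 and a 0.6 rad lag
— reproducing the observed roughly 110° shank excursion for a 60° thigh
range. The true free-swing dynamics of such a rig are not modelled; the
coupled sinusoid reproduces only the excursion ratio and phase character.
Streams are produced at two attachment radii per bar to emulate different
mounting positions.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: soft-tissue and skin-mounted sensor artifact,
out-of-plane (frontal/transverse) motion, magnetometer-free heading drift
in 3-D, scale-factor and cross-axis sensor errors, kinematic loop closure
(the foot trajectory and the thigh–shank chain are parameterized
independently), and inter-subject waveform variability. Accuracy numbers
from the acceptance script are statements about this simulation at its
documented noise defaults, not field performance. One known artifact of
the half-cycle phase offset between legs: during the standing lead-in the
*right* foot is frozen mid-swing, so right-foot stride analysis lacks a
clean initial rest baseline; stride evaluation uses the left foot, and
right-leg joint estimation is unaffected (any static pose anchors θ₀).

## Numerical choices and degenerate inputs

Trapezoidal quadrature everywhere an integral appears; causal filtering
with DC-steady-state initialization (a 12/cutoff-second constant pad, long
enough that the transient decays below double precision); two-argument
arctangents for all tilt angles, with a free-fall error when both gravity
components vanish below 1e-6 G; covariance updates in Joseph form with a
symmetrization step; timestamps must be strictly increasing and within 20%
of the nominal interval in the median; acceleration magnitudes are
sanity-bounded at 16 G; timing jitter in the noise model is truncated at
40% of a sample so monotonicity survives. Empty streams, header-only
files, rest-only trials (no strides), constant series (undefined
correlation → `NA`), and missing extrema in a characteristic-point window
(→ `NA`, never fabricated) are all defined outcomes rather than errors.

The ten characteristic points use fixed, documented phase windows — there
is no canonical delimitation, so reproducibility is preferred over
case-by-case judgement: swing = the detected
movement interval; stance = movement end to next onset (or end of
recording for the final stride); heel strike = ±10% of stride duration
around the stance onset; double knee action = first knee local maximum in
the first 40% of stance; mid-stance = the middle third of stance.
Correlations with stride velocity and length are Pearson throughout, with
no significance machinery.

## Problem sizes

The test suite and acceptance script run, as the package's chosen
evaluation sizes: 20 seeded 90 s walking trials for joint-angle RMSE/CC
(knee and hip, left side), 20 seeded 10-stride walks for stride-length
error (first strides excluded), and 5 × 60 s pendulum trials per speed
condition. Property checks (drift rejection, ZUPT exactness, yaw
invariance, noise monotonicity) use shorter trials with fixed seeds.

## Known limitations

Ankle-angle accuracy is inherently weaker than hip/knee: the foot's
accelerometer spends much of the cycle far from rest, and its excursions
are small relative to the drift-correction band — consistent with this
method family's reported experience. The stride pipeline assumes the x–z
sensor plane is sagittal; large mounting roll is not corrected. The Kalman
defaults are tuned to the generator's conditions and should be revisited
(via `kalman_params()`) for sensors with substantially different noise, and
the characteristic-point windows, while reproducible, are conventions
rather than validated clinical definitions.
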