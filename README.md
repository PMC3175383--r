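# imugait

Sagittal-plane gait evaluation from body-worn inertial sensors: lower-limb
joint angles by Kalman-filtered gyroscope/accelerometer fusion, and
per-stride length and velocity from a foot-mounted IMU with automatic
stationary-state detection. The package is aimed at movement-science and
rehabilitation-engineering work where a camera-based motion lab is
unavailable: a handful of wireless sensors (feet, shanks, thighs, lumbar;
accelerometers in G, gyroscopes in deg/s, nominally 100 Hz) stand in for the
optical system.

Because no public IMU + ground-truth dataset accompanies this measurement
setup, the package ships a first-class synthetic signal generator that
produces planar walking and rigid-body duplex-pendulum trials with exact
ground-truth joint angles and stride lengths; every accuracy claim the
package makes is measured against that generator.

## Methods in brief

**Joint angles.** A sagittal joint angle is the difference of the adjacent
segments' tilt angles. Gyro integration gives

θ(t) = ∫ (ω_prox − ω_dist) dt + θ₀,

with θ₀ from the accelerometer tilt difference at rest,
θ_seg = tan⁻¹-style angle of the measured gravity vector in the segment's
x–z plane. Integration drifts with gyroscope offset; the accelerometer
angle is drift-free but corrupted by movement acceleration. An error-state
Kalman filter fuses them: the state is the angle error Δθ and the
per-sample bias increment Δb,

x_{k+1} = F x_k + [w, w]ᵀ,  F = [[1, Δt], [0, 1]],  Δy_k = [1, 0] x_k + v,

where Δy is the slow discrepancy between the gyro-propagated and
accelerometer-measured gravity directions (both passed through the same
causal 0.5 Hz 2nd-order Butterworth low-pass), and the corrected angle is
θ̂ = θ − Δθ̂.

**Stride length.** The foot is stationary during foot-flat; movement is
detected when the sum over the three accelerometer axes of |acceleration −
rest baseline| exceeds 0.15 G for 3 consecutive samples, and ends at the
first sub-threshold sample of a forward window of 10 samples containing at
least 3 sub-threshold samples. Over each movement interval the foot pitch
from gyro integration (seeded by θ_init = mean of 6 arcsin(a_x/g) rest
samples) tilt-compensates the accelerations, the horizontal velocity
v_h = ∫ (a_x cos θ − a_z sin θ) dτ is integrated from zero, corrected
linearly so v(T) = 0 (zero-velocity update), and the stride length is

L = √( (∫ v_h)² + (∫ v_y)² ),

the lateral term correcting sensor yaw misalignment with the direction of
travel.

## Worked example

```r
library(imugait)

trial <- simulate_walk(gait_model_params(n_strides = 12),
                       sensor_noise_params(seed = 42))
knee <- estimate_joint_angle(trial$streams$left_thigh,
                             trial$streams$left_shank, "knee")
truth <- subset(trial$truth_angles, side == "left" & joint == "knee")
agreement(knee$theta_hat,  truth$angle_deg, joint = "knee", side = "left")
#>    rmse    cc     n joint side
#> 1  2.00 0.998  1504 knee  left
agreement(knee$theta_gyro, truth$angle_deg, joint = "knee", side = "left")
#>    rmse    cc     n joint side
#> 1  2.97 0.996  1504 knee  left
```

The Kalman-corrected knee angle tracks the ground truth with 2.0 deg RMSE
and correlation 0.998 on this 16 s noisy trial, against 3.0 deg for raw
gyro integration — the gap widens with trial length as the raw integral
drifts (`autoplot(knee)` shows the three traces). The foot stream yields
per-stride spatiotemporal parameters:

```r
strides <- analyze_gait(trial$streams$left_foot)
glance(strides)
#>   n_strides n_retained mean_length_m sd_length_m mean_duration_s ...
#> 1        12         11          1.40     0.00330           0.709
```

Mean estimated stride length 1.40 m against a ground truth of exactly
1.40 m per stride (the first stride is excluded from the summary, as it
starts from standstill). `extract_points()` then reduces each stride to ten
characteristic joint-angle values (peak flexions/extensions per phase) and
`correlate_points()` relates them to stride velocity and length.

A thin command-line front end wrapping these functions is installed at
`system.file("cli", "imugait", package = "imugait")` with subcommands
`synth`, `angles`, `stride`, and `report`.

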