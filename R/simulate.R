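## ---- harmonic waveforms -----------------------------------------------
## A periodic waveform is stored as a DC term plus <= 4 complex Fourier
## coefficients; evaluation and differentiation (w.r.t. cycle phase) are
## closed-form, so segment angular rates and accelerations are analytic.

fit_harmonics <- function(f, n_harm = 4, n_grid = 512) {
  phi <- (seq_len(n_grid) - 1) / n_grid
  v <- f(phi)
  list(a0 = mean(v),
       c = vapply(seq_len(n_harm), function(k) {
         mean(v * exp(-2i * pi * k * phi))
       }, complex(1)))
}

harm_eval <- function(h, phi, deriv = 0) {
  out <- if (deriv == 0) rep(h$a0, length(phi)) else numeric(length(phi))
  for (k in seq_along(h$c)) {
    ck <- h$c[k] * (2i * pi * k)^deriv
    out <- out + 2 * Re(ck * exp(2i * pi * k * phi))
  }
  out
}

## linear rescale of a harmonic waveform so its extrema hit `range`
harm_rescale <- function(h, range) {
  phi <- (0:2047) / 2048
  v <- harm_eval(h, phi)
  a <- diff(range) / (max(v) - min(v))
  h$c <- h$c * a
  h$a0 <- range[1] + a * (h$a0 - min(v))
  h
}

## smooth compact bump on [c-w, c+w]: cos^2 window, C1 at the edges
bump <- function(u, c, w) {
  ifelse(abs(u - c) < w, cos(pi * (u - c) / (2 * w))^2, 0)
}
bump_d <- function(u, c, w) {
  ifelse(abs(u - c) < w, -pi / (2 * w) * sin(pi * (u - c) / w), 0)
}

## minimum-jerk-style displacement pulse: integral 1, zero value and slope
## at both ends
wpulse <- function(u) 30 * u^2 * (1 - u)^2
wpulse_d <- function(u) 60 * u * (1 - u) * (1 - 2 * u)
wpulse_I <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

## ---- parameter objects ------------------------------------------------

#' Walking-model parameters for the synthetic gait generator
#'
#' The generator builds planar lower-limb kinematics from smooth periodic
#' joint waveforms (harmonic approximations of common gait curves) and a
#' foot trajectory with an exactly stationary foot-flat dwell each stance
#' phase, then synthesizes what each body-worn sensor would measure. A
#' trial starts with `lead_in_s` seconds of quiet standing and ramps
#' smoothly up to the cyclic gait.
#'
#' @param stride_length_m Ground-truth length of every stride (default 1.4).
#' @param cadence_steps_per_min Steps (both feet) per minute; the stride
#'   period is `120/cadence` seconds (default 110).
#' @param stance_fraction Fraction of the cycle the foot is on the ground
#'   (default 0.6); the exactly-stationary foot-flat dwell is
#'   `stance_fraction - 0.25` of the cycle, the remainder being the
#'   push-off and landing transitions.
#' @param hip_range,knee_range,ankle_range Waveform amplitude ranges in deg
#'   (`c(min, max)`). `ankle_range` scales the foot-pitch excursions that
#'   generate plantar-/dorsiflexion.
#' @param thigh_length_m,shank_length_m Segment lengths.
#' @param thigh_radius_m,shank_radius_m,lumbar_radius_m Sensor attachment
#'   distances from the proximal joint.
#' @param foot_lift_m Peak foot elevation during swing (default 0.08).
#' @param n_strides Number of complete strides per foot.
#' @param lead_in_s,ramp_s Quiet-standing lead-in and smooth speed ramp.
#' @param seed Optional RNG seed (used when the noise model has none).
#' @return A list of class `gait_model_params`.
#' @export
gait_model_params <- function(stride_length_m = 1.4,
                              cadence_steps_per_min = 110,
                              stance_fraction = 0.6,
                              hip_range = c(-10, 30),
                              knee_range = c(0, 60),
                              ankle_range = c(-15, 10),
                              thigh_length_m = 0.40,
                              shank_length_m = 0.40,
                              thigh_radius_m = 0.22,
                              shank_radius_m = 0.18,
                              lumbar_radius_m = 0.15,
                              foot_lift_m = 0.08,
                              n_strides = 10,
                              lead_in_s = 1.0, ramp_s = 1.5,
                              seed = NULL) {
  stopifnot(stride_length_m > 0, cadence_steps_per_min > 0,
            stance_fraction > 0, stance_fraction < 1, n_strides >= 1)
  if (foot_lift_m <= 0) abort("foot penetration below ground: foot_lift_m must be positive")
  structure(as.list(environment()), class = "gait_model_params")
}

#' Rigid-body duplex-pendulum parameters
#'
#' Emulates a two-joint rig: the thigh segment is driven sinusoidally from a
#' fixed pivot at a metronome tempo, and the shank responds passively with a
#' larger excursion (coupling gain) and a phase lag, as observed on such
#' rigs. Each trial draws its total thigh excursion uniformly within
#' `thigh_range_deg`. Sensors are synthesized at two attachment radii per
#' segment to emulate different attachment positions along the bar.
#'
#' @param thigh_range_deg Total thigh excursion bounds in deg, e.g.
#'   `c(30, 40)` (slow), `c(50, 60)` (normal), `c(70, 80)` (fast).
#' @param tempo_bpm Metronome tempo; one beat per half-cycle (default 90).
#' @param duration_s Trial length in seconds of steady movement (default 60).
#' @param coupling_gain Shank/thigh excursion ratio (default 1.8).
#' @param coupling_lag_rad Shank phase lag (default 0.6).
#' @param thigh_length_m Distance from the fixed pivot to the knee joint.
#' @param thigh_radii_m,shank_radii_m Two sensor attachment radii per
#'   segment (nominal first).
#' @param lead_in_s,ramp_s Static lead-in and smooth start-up ramp.
#' @param seed Optional RNG seed.
#' @return A list of class `pendulum_params`.
#' @export
pendulum_params <- function(thigh_range_deg = c(50, 60), tempo_bpm = 90,
                            duration_s = 60, coupling_gain = 1.8,
                            coupling_lag_rad = 0.6, thigh_length_m = 0.40,
                            thigh_radii_m = c(0.12, 0.28),
                            shank_radii_m = c(0.10, 0.25),
                            lead_in_s = 1.0, ramp_s = 1.5, seed = NULL) {
  stopifnot(length(thigh_range_deg) == 2,
            thigh_range_deg[1] < thigh_range_deg[2],
            tempo_bpm > 0, duration_s > 0, coupling_gain > 0)
  structure(as.list(environment()), class = "pendulum_params")
}

#' Sensor noise model
#'
#' Gyroscope channels receive a constant per-trial offset (drawn
#' `N(0, gyro_bias0^2)` per axis), a bias random walk, and white noise;
#' accelerometer channels receive white noise. Optional timing jitter
#' perturbs the time stamps (truncated at 40% of the sampling interval so
#' monotonicity is preserved). The defaults model the offset-drift problem
#' that motivates Kalman correction of integrated gyro angles.
#'
#' @param gyro_white_sd White noise SD, deg/s (default 0.5).
#' @param gyro_bias_walk_sd Bias random-walk intensity, deg/s per sqrt(s)
#'   (default 0.02).
#' @param gyro_bias0 SD of the constant initial bias, deg/s (default 0.3).
#' @param accel_white_sd Accelerometer white noise SD, G (default 0.02).
#' @param timing_jitter_sd Time-stamp jitter SD, ms (default 0).
#' @param seed RNG seed; same seed, same trial, bit for bit.
#' @return A list of class `sensor_noise_params`.
#' @export
sensor_noise_params <- function(gyro_white_sd = 0.5,
                                gyro_bias_walk_sd = 0.02,
                                gyro_bias0 = 0.3,
                                accel_white_sd = 0.02,
                                timing_jitter_sd = 0,
                                seed = NULL) {
  stopifnot(gyro_white_sd >= 0, gyro_bias_walk_sd >= 0, gyro_bias0 >= 0,
            accel_white_sd >= 0, timing_jitter_sd >= 0)
  structure(as.list(environment()), class = "sensor_noise_params")
}

#' Noise-free sensor model
#' @return A [sensor_noise_params()] with every noise term zero.
#' @export
noise_off <- function() {
  sensor_noise_params(0, 0, 0, 0, 0, seed = 1L)
}

## ---- shared machinery --------------------------------------------------

## smoothstep speed ramp: returns s (warped time), s_dot, s_ddot
time_warp <- function(t, lead, ramp) {
  u <- pmin(pmax((t - lead) / ramp, 0), 1)
  s_dot <- 3 * u^2 - 2 * u^3
  s <- ifelse(t <= lead, 0,
              ifelse(u < 1, ramp * (u^3 - u^4 / 2),
                     ramp / 2 + (t - lead - ramp)))
  s_ddot <- ifelse(u > 0 & u < 1, (6 * u - 6 * u^2) / ramp, 0)
  list(s = s, s_dot = s_dot, s_ddot = s_ddot)
}

## specific force of a point with world acceleration (aX, aZ), projected
## into a limb segment frame at tilt theta (deg); returns G units
limb_specific_force <- function(aX, aZ, theta_deg) {
  th <- theta_deg * pi / 180
  fx <- aX / G_MS2
  fz <- aZ / G_MS2 + 1
  list(ax = fx * cos(th) + fz * sin(th),
       az = fx * sin(th) - fz * cos(th))
}

## world acceleration of a point offset r along a rotating segment
## (theta in deg, rates in deg/s, deg/s^2): d^2/dt^2 of r*(sin, -cos)
segment_point_accel <- function(r, theta, theta_dot, theta_ddot) {
  th <- theta * pi / 180
  thd <- theta_dot * pi / 180
  thdd <- theta_ddot * pi / 180
  list(aX = r * (cos(th) * thdd - sin(th) * thd^2),
       aZ = r * (sin(th) * thdd + cos(th) * thd^2))
}

make_limb_stream <- function(t, segment, theta, theta_dot, aX, aZ,
                             accel_motion = TRUE) {
  if (!accel_motion) {
    aX <- aZ <- numeric(length(t))
  }
  f <- limb_specific_force(aX, aZ, theta)
  imu_stream(tibble(t = t, ax = f$ax, ay = 0, az = f$az,
                    wx = 0, wy = theta_dot, wz = 0),
             segment = segment, check = FALSE)
}

apply_sensor_noise <- function(stream, noise) {
  n <- nrow(stream)
  dt <- stream_dt(stream)
  out <- as_tibble(stream)
  for (ch in c("wx", "wy", "wz")) {
    if (all(is.na(out[[ch]]))) next
    bias0 <- stats::rnorm(1, 0, noise$gyro_bias0)
    walk <- cumsum(stats::rnorm(n, 0, noise$gyro_bias_walk_sd * sqrt(dt)))
    out[[ch]] <- out[[ch]] + bias0 + walk +
      stats::rnorm(n, 0, noise$gyro_white_sd)
  }
  for (ch in c("ax", "ay", "az")) {
    if (all(is.na(out[[ch]]))) next
    out[[ch]] <- out[[ch]] + stats::rnorm(n, 0, noise$accel_white_sd)
  }
  if (noise$timing_jitter_sd > 0) {
    j <- stats::rnorm(n, 0, noise$timing_jitter_sd / 1000)
    j <- pmin(pmax(j, -0.4 * dt), 0.4 * dt)
    out$t <- out$t + j
  }
  imu_stream(out, segment = seg_attr(stream),
             nominal_rate = attr(stream, "nominal_rate"), check = FALSE)
}

## ---- walking ----------------------------------------------------------

walk_waveforms <- function(gait) {
  hip <- harm_rescale(fit_harmonics(function(phi) {
    cos(2 * pi * (phi - 0.97)) + 0.12 * cos(4 * pi * phi - 0.6)
  }), gait$hip_range)
  knee <- harm_rescale(fit_harmonics(function(phi) {
    0.28 * exp(6 * (cos(2 * pi * (phi - 0.05)) - 1)) +
      exp(5 * (cos(2 * pi * (phi - 0.63)) - 1))
  }), gait$knee_range)
  trunk <- fit_harmonics(function(phi) 1.5 * cos(4 * pi * phi - 0.4))
  list(hip = hip, knee = knee, trunk = trunk)
}

## foot pitch (deg, toe-up positive) over the movement window u in [0,1]
foot_pitch <- function(u, gait) {
  a_po <- 55 * abs(gait$ankle_range[1]) / 15
  a_hs <- 12 * abs(gait$ankle_range[2]) / 10
  ## bump supports lie strictly inside the movement window, so pitch and
  ## pitch rate are continuous (and zero) at both dwell boundaries
  list(beta = -a_po * bump(u, 0.25, 0.25) + a_hs * bump(u, 0.80, 0.20),
       dbeta = -a_po * bump_d(u, 0.25, 0.25) + a_hs * bump_d(u, 0.80, 0.20))
}

## foot kinematics for one side at cycle phase phi (may be negative before
## the side's first cycle); d = dwell fraction
foot_kinematics <- function(phi, phi_dot, phi_ddot, gait, d) {
  L <- gait$stride_length_m
  H <- gait$foot_lift_m
  cyc <- floor(phi)
  frac <- phi - cyc
  moving <- frac >= d
  u <- pmax((frac - d) / (1 - d), 0)
  u_dot <- ifelse(moving, phi_dot / (1 - d), 0)
  u_ddot <- ifelse(moving, phi_ddot / (1 - d), 0)

  x <- L * (cyc + ifelse(moving, wpulse_I(u), 0))
  vx <- ifelse(moving, L * wpulse(u) * u_dot, 0)
  axl <- ifelse(moving, L * (wpulse_d(u) * u_dot^2 + wpulse(u) * u_ddot), 0)

  z <- ifelse(moving, H * sin(pi * u)^2, 0)
  vz <- ifelse(moving, H * pi * sin(2 * pi * u) * u_dot, 0)
  azl <- ifelse(moving,
                H * (2 * pi^2 * cos(2 * pi * u) * u_dot^2 +
                       pi * sin(2 * pi * u) * u_ddot), 0)

  fp <- foot_pitch(u, gait)
  beta <- ifelse(moving, fp$beta, 0)
  dbeta <- ifelse(moving, fp$dbeta * u_dot, 0)
  list(x = x, vx = vx, ax = axl, z = z, vz = vz, az = azl,
       beta = beta, beta_dot = dbeta, moving = moving, cyc = cyc)
}

make_foot_stream <- function(t, segment, fk, accel_motion = TRUE) {
  b <- fk$beta * pi / 180
  aX <- if (accel_motion) fk$ax else numeric(length(t))
  aZ <- if (accel_motion) fk$az else numeric(length(t))
  fx <- aX / G_MS2
  fz <- aZ / G_MS2 + 1
  ## foot frame: x anterior along the foot, z dorsal
  imu_stream(tibble(t = t,
                    ax = fx * cos(b) + fz * sin(b), ay = 0,
                    az = -fx * sin(b) + fz * cos(b),
                    wx = 0, wy = fk$beta_dot, wz = 0),
             segment = segment, check = FALSE)
}

#' Simulate a synthetic walking trial with ground truth
#'
#' Generates the seven body-worn sensor streams (both feet, shanks, thighs,
#' and the lumbar sensor) for a planar walking trial, together with exact
#' ground-truth joint angles and stride lengths. The trial starts with quiet
#' standing, ramps smoothly into a strictly periodic gait, and every stance
#' phase contains an exactly stationary foot-flat dwell, so the
#' stationary-state detector has a true rest state. Gyroscope channels are
#' the analytic segment pitch rates plus the noise model; accelerometer
#' channels are the analytic specific force (gravity plus sensor-point
#' linear acceleration, projected into the segment frame) plus white noise.
#'
#' @param gait A [gait_model_params()].
#' @param noise A [sensor_noise_params()].
#' @param accel_motion If `FALSE` the accelerometers see gravity only (no
#'   linear acceleration) — a diagnostic mode in which accelerometer tilt
#'   is exact.
#' @param rate Sampling rate in Hz (default 100).
#' @return A list of class `synthetic_trial`: `streams` (named list of
#'   [imu_stream()]), `truth_angles` (tibble `t`, `side`, `joint`,
#'   `angle_deg`), `truth_strides` (tibble `side`, `stride_index`,
#'   `t_start`, `t_end`, `length_m`), and `params`.
#' @export
simulate_walk <- function(gait = gait_model_params(),
                          noise = sensor_noise_params(),
                          accel_motion = TRUE, rate = 100) {
  seed <- noise$seed %||% gait$seed %||% 1L
  withr::with_seed(as.integer(seed), {
    T_ <- 120 / gait$cadence_steps_per_min
    d <- gait$stance_fraction - 0.25
    stopifnot(d > 0)
    s_end <- (gait$n_strides + 0.5 * d) * T_
    t_end <- gait$lead_in_s + gait$ramp_s + (s_end - gait$ramp_s / 2)
    t <- seq(0, t_end, by = 1 / rate)
    wp <- time_warp(t, gait$lead_in_s, gait$ramp_s)
    phi <- wp$s / T_
    phi_dot <- wp$s_dot / T_
    phi_ddot <- wp$s_ddot / T_
    wf <- walk_waveforms(gait)

    ## pelvis trajectory
    vbar <- gait$stride_length_m / T_
    pX <- vbar * wp$s + 0.01 * sin(4 * pi * phi - 0.3)
    aPX <- 0.01 * (-16 * pi^2 * sin(4 * pi * phi - 0.3) * phi_dot^2 +
                     4 * pi * cos(4 * pi * phi - 0.3) * phi_ddot) +
      vbar * wp$s_ddot
    aPZ <- 0.02 * (-16 * pi^2 * cos(4 * pi * phi + 0.2) * phi_dot^2 -
                     4 * pi * sin(4 * pi * phi + 0.2) * phi_ddot)

    trunk <- list(th = harm_eval(wf$trunk, phi),
                  d1 = harm_eval(wf$trunk, phi, 1) * phi_dot,
                  d2 = harm_eval(wf$trunk, phi, 2) * phi_dot^2 +
                    harm_eval(wf$trunk, phi, 1) * phi_ddot)

    side_kin <- function(offset) {
      ph <- phi - offset
      hip <- list(th = harm_eval(wf$hip, ph),
                  d1 = harm_eval(wf$hip, ph, 1) * phi_dot,
                  d2 = harm_eval(wf$hip, ph, 2) * phi_dot^2 +
                    harm_eval(wf$hip, ph, 1) * phi_ddot)
      knee <- list(th = harm_eval(wf$knee, ph),
                   d1 = harm_eval(wf$knee, ph, 1) * phi_dot,
                   d2 = harm_eval(wf$knee, ph, 2) * phi_dot^2 +
                     harm_eval(wf$knee, ph, 1) * phi_ddot)
      thigh <- list(th = hip$th + trunk$th, d1 = hip$d1 + trunk$d1,
                    d2 = hip$d2 + trunk$d2)
      shank <- list(th = thigh$th - knee$th, d1 = thigh$d1 - knee$d1,
                    d2 = thigh$d2 - knee$d2)
      fk <- foot_kinematics(ph, phi_dot, phi_ddot, gait, d)
      list(hip = hip, knee = knee, thigh = thigh, shank = shank, foot = fk)
    }
    left <- side_kin(0)
    right <- side_kin(0.5)

    streams <- list()
    streams$lumbar <- local({
      pa <- segment_point_accel(-gait$lumbar_radius_m, trunk$th, trunk$d1,
                                trunk$d2)
      make_limb_stream(t, "lumbar", trunk$th, trunk$d1,
                       aPX + pa$aX, aPZ + pa$aZ, accel_motion)
    })
    for (side in c("left", "right")) {
      k <- if (side == "left") left else right
      pa_t <- segment_point_accel(gait$thigh_radius_m, k$thigh$th,
                                  k$thigh$d1, k$thigh$d2)
      streams[[paste0(side, "_thigh")]] <- make_limb_stream(
        t, paste0(side, "_thigh"), k$thigh$th, k$thigh$d1,
        aPX + pa_t$aX, aPZ + pa_t$aZ, accel_motion)
      pa_k <- segment_point_accel(gait$thigh_length_m, k$thigh$th,
                                  k$thigh$d1, k$thigh$d2)
      pa_s <- segment_point_accel(gait$shank_radius_m, k$shank$th,
                                  k$shank$d1, k$shank$d2)
      streams[[paste0(side, "_shank")]] <- make_limb_stream(
        t, paste0(side, "_shank"), k$shank$th, k$shank$d1,
        aPX + pa_k$aX + pa_s$aX, aPZ + pa_k$aZ + pa_s$aZ, accel_motion)
      streams[[paste0(side, "_foot")]] <- make_foot_stream(
        t, paste0(side, "_foot"), k$foot, accel_motion)
    }
    streams <- lapply(streams, apply_sensor_noise, noise = noise)

    truth_angles <- dplyr::bind_rows(lapply(c("left", "right"), function(side) {
      k <- if (side == "left") left else right
      dplyr::bind_rows(
        tibble(t = t, side = side, joint = "hip", angle_deg = k$hip$th),
        tibble(t = t, side = side, joint = "knee", angle_deg = k$knee$th),
        tibble(t = t, side = side, joint = "ankle",
               angle_deg = k$foot$beta - k$shank$th)
      )
    }))

    ## stride k of a side moves over warped time ((k-1+offset+d)T, (k+offset)T)
    t_of_s <- function(sq) stats::approx(wp$s, t, xout = sq, ties = "ordered")$y
    truth_strides <- dplyr::bind_rows(lapply(c("left", "right"), function(side) {
      off <- if (side == "left") 0 else 0.5
      ks <- seq_len(gait$n_strides - (side == "right"))
      tibble(side = side, stride_index = ks,
             t_start = t_of_s(((ks - 1) + off + d) * T_),
             t_end = t_of_s((ks + off) * T_),
             length_m = gait$stride_length_m)
    }))

    structure(list(streams = streams, truth_angles = truth_angles,
                   truth_strides = truth_strides,
                   params = list(gait = gait, noise = noise,
                                 accel_motion = accel_motion, rate = rate,
                                 stride_period_s = T_, dwell_fraction = d)),
              class = "synthetic_trial")
  })
}

## ---- duplex pendulum --------------------------------------------------

#' Simulate the rigid-body duplex pendulum
#'
#' A two-joint rig: the thigh bar swings sinusoidally from a fixed pivot at
#' the metronome tempo (one beat per half-cycle), with its total excursion
#' drawn uniformly within `thigh_range_deg`; the shank bar responds with a
#' larger excursion (`coupling_gain`) and a phase lag. The knee angle is the
#' difference of the two bar angles. Sensors are synthesized at two
#' attachment radii on each bar (streams `left_*` at the nominal radius,
#' `right_*` at the alternate radius — same angular motion, different linear
#' acceleration).
#'
#' @param p A [pendulum_params()].
#' @param noise A [sensor_noise_params()].
#' @param accel_motion As in [simulate_walk()].
#' @param rate Sampling rate in Hz.
#' @return A `synthetic_trial` (truth joints `hip` and `knee`, no strides).
#' @export
simulate_pendulum <- function(p = pendulum_params(),
                              noise = sensor_noise_params(),
                              accel_motion = TRUE, rate = 100) {
  seed <- noise$seed %||% p$seed %||% 1L
  withr::with_seed(as.integer(seed), {
    exc <- stats::runif(1, p$thigh_range_deg[1], p$thigh_range_deg[2])
    A_t <- exc / 2
    A_s <- p$coupling_gain * A_t
    f <- p$tempo_bpm / 120  # two beats per full cycle
    w <- 2 * pi * f
    t <- seq(0, p$lead_in_s + p$ramp_s + p$duration_s, by = 1 / rate)
    wp <- time_warp(t, p$lead_in_s, p$ramp_s)

    ang <- function(A, lag) {
      list(th = A * sin(w * wp$s - lag),
           d1 = A * w * cos(w * wp$s - lag) * wp$s_dot,
           d2 = A * (-w^2 * sin(w * wp$s - lag) * wp$s_dot^2 +
                       w * cos(w * wp$s - lag) * wp$s_ddot))
    }
    thigh <- ang(A_t, 0)
    shank <- ang(A_s, p$coupling_lag_rad)

    streams <- list()
    for (i in 1:2) {
      side <- c("left", "right")[i]
      pa_t <- segment_point_accel(p$thigh_radii_m[i], thigh$th, thigh$d1,
                                  thigh$d2)
      streams[[paste0(side, "_thigh")]] <- make_limb_stream(
        t, paste0(side, "_thigh"), thigh$th, thigh$d1, pa_t$aX, pa_t$aZ,
        accel_motion)
      pa_k <- segment_point_accel(p$thigh_length_m, thigh$th, thigh$d1,
                                  thigh$d2)
      pa_s <- segment_point_accel(p$shank_radii_m[i], shank$th, shank$d1,
                                  shank$d2)
      streams[[paste0(side, "_shank")]] <- make_limb_stream(
        t, paste0(side, "_shank"), shank$th, shank$d1,
        pa_k$aX + pa_s$aX, pa_k$aZ + pa_s$aZ, accel_motion)
    }
    streams <- lapply(streams, apply_sensor_noise, noise = noise)

    truth_angles <- dplyr::bind_rows(
      tibble(t = t, side = "left", joint = "hip", angle_deg = thigh$th),
      tibble(t = t, side = "left", joint = "knee",
             angle_deg = thigh$th - shank$th)
    )
    structure(list(streams = streams, truth_angles = truth_angles,
                   truth_strides = tibble(side = character(),
                                          stride_index = integer(),
                                          t_start = numeric(),
                                          t_end = numeric(),
                                          length_m = numeric()),
                   params = list(pendulum = p, noise = noise,
                                 excursion_deg = exc,
                                 accel_motion = accel_motion, rate = rate)),
              class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial: %d streams, %d samples, %d truth strides>\n",
              length(x$streams), nrow(x$streams[[1]]),
              nrow(x$truth_strides)))
  invisible(x)
}
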