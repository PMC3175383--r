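# Shared fixtures and small helpers. Trials are generated once per test run.

uniform_stream <- function(n, segment = "left_thigh", ax = 0, ay = 0, az = -1,
                           wy = 0, rate = 100) {
  imu_stream(tibble::tibble(t = (seq_len(n) - 1) / rate, ax = ax, ay = ay,
                            az = az, wx = 0, wy = wy, wz = 0),
             segment = segment, nominal_rate = rate)
}

# knee or hip estimate + truth agreement for a synthetic trial
trial_joint_agreement <- function(tr, joint, side = "left",
                                  params = kalman_params()) {
  st <- tr$streams
  pr <- switch(joint, knee = st[[paste0(side, "_thigh")]], hip = st$lumbar)
  di <- switch(joint, knee = st[[paste0(side, "_shank")]],
               hip = st[[paste0(side, "_thigh")]])
  est <- estimate_joint_angle(pr, di, joint, params)
  truth <- tr$truth_angles[tr$truth_angles$side == side &
                             tr$truth_angles$joint == joint, ]
  agreement(est$theta_hat, truth$angle_deg, joint, side)
}

# pendulum knee agreement at the nominal sensor radii
pendulum_knee_agreement <- function(tr, params = kalman_params()) {
  est <- estimate_joint_angle(tr$streams$left_thigh, tr$streams$left_shank,
                              "knee", params)
  truth <- tr$truth_angles[tr$truth_angles$joint == "knee", ]
  agreement(est$theta_hat, truth$angle_deg, "knee", "left")
}

# stride-length percent errors (retained strides) for one walking trial
stride_pct_errors <- function(tr, side = "left") {
  g <- analyze_gait(tr$streams[[paste0(side, "_foot")]])
  keep <- g[!g$first_stride & !g$end_not_detected, ]
  truth <- tr$truth_strides[tr$truth_strides$side == side, ]
  m <- merge(keep, truth, by = "stride_index")
  abs(m$length_m.x - m$length_m.y) / m$length_m.y * 100
}

# small cached zero-noise trials
walk_zero <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_walk(gait_model_params(n_strides = 8), noise_off())
    }
    val
  }
})

walk_zero_gravity <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_walk(gait_model_params(n_strides = 8), noise_off(),
                            accel_motion = FALSE)
    }
    val
  }
})
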