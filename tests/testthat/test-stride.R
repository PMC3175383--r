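test_that("movement scalar is zero at rest and reflects deviations", {
  st <- uniform_stream(200, segment = "left_foot", ax = 0.1, ay = -0.05,
                       az = 0.99)
  s <- movement_signal(st)
  expect_equal(s$s, rep(0, 200))

  st$ax[100] <- st$ax[100] + 0.3
  s <- movement_signal(st)
  expect_equal(s$s[100], 0.3)
  expect_equal(s$s[99], 0)
})

test_that("step detection follows the onset and 3-of-10 end rules", {
  s <- c(0, 0, .2, .2, .2, rep(0, 10))
  iv <- detect_steps(s)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$i_start, 3L)  # first of the 3 consecutive supra-threshold
  expect_equal(iv$i_end, 6L)    # first sub-threshold sample of the window

  expect_equal(nrow(detect_steps(rep(0, 50))), 0L)

  two <- c(rep(0, 10), rep(.5, 20), rep(0, 50), rep(.5, 20), rep(0, 12))
  iv <- detect_steps(two)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$i_start, c(11L, 81L))
  expect_true(all(iv$i_end > iv$i_start))
  expect_true(all(diff(iv$i_start) > 0))

  ## trailing movement without an end is flagged
  iv <- detect_steps(c(rep(0, 10), rep(.5, 20)))
  expect_false(iv$end_detected[nrow(iv)])

  ## joint rescaling of signal and threshold leaves detection unchanged
  a <- detect_steps(two, detection_params(accel_thresh_G = 0.15))
  b <- detect_steps(two * 7, detection_params(accel_thresh_G = 0.15 * 7))
  expect_identical(a, b)
})

test_that("horizontal velocity integrates tilt-compensated acceleration", {
  ## flat foot, constant 0.1 G forward for 1 s -> 0.981 m/s
  st <- uniform_stream(121, segment = "left_foot", ax = 0.1, az = 1)
  iv <- tibble::tibble(i_start = 11L, i_end = 111L, end_detected = TRUE)
  v <- horizontal_velocity(st, iv, theta_init = 0)
  expect_equal(v$v[nrow(v)], 0.1 * 9.80665, tolerance = 1e-9)

  ## at 90 deg tilt the x-axis is vertical: no horizontal pickup
  st <- uniform_stream(121, segment = "left_foot", ax = 0.4, az = 0)
  v <- horizontal_velocity(st, iv, theta_init = 90)
  expect_lt(max(abs(v$v)), 1e-9)
  expect_error(horizontal_velocity(st, tibble::tibble(i_start = 5L,
                                                      i_end = 6L), 0),
               "3 samples")
})

test_that("linear ZUPT correction is exact for linear drift", {
  t <- seq(0, 1, 0.01)
  v <- sin(pi * t)^2 * 0
  expect_equal(zupt_linear_correction(v, t), v)

  drift <- 0.2 * t / max(t)
  expect_equal(zupt_linear_correction(drift, t), rep(0, length(t)))

  truth <- sin(pi * t)^2  # zero at both ends
  expect_equal(zupt_linear_correction(truth + drift, t), truth,
               tolerance = 1e-12)
  expect_error(zupt_linear_correction(c(0, 1), c(1, 1)), "positive")
})

test_that("stride length combines forward and lateral displacements", {
  ## sinusoidal accelerations whose corrected velocities integrate to 3 and
  ## 4 m -> length 5 (Euclidean norm)
  rate <- 100
  n_rest <- 60
  Tm <- 1
  n_mov <- Tm * rate
  t <- (seq_len(n_rest + n_mov + 20) - 1) / rate
  u <- pmin(pmax((t - n_rest / rate) / Tm, 0), 1)
  axw <- 3 * 2 * pi / Tm^2 * sin(2 * pi * u) / 9.80665
  ayw <- 4 * 2 * pi / Tm^2 * sin(2 * pi * u) / 9.80665
  st <- imu_stream(tibble::tibble(t = t, ax = axw, ay = ayw, az = 1,
                                  wx = 0, wy = 0, wz = 0), "left_foot")
  iv <- tibble::tibble(i_start = n_rest + 1L, i_end = n_rest + n_mov + 1L,
                       t_start = t[n_rest + 1], t_end = t[n_rest + n_mov + 1],
                       end_detected = TRUE)
  rec <- stride_length(st, iv)
  expect_equal(rec$length_m, 5, tolerance = 1e-3)
  expect_equal(rec$velocity_mps, rec$length_m / rec$duration_s)

  ## without lateral acceleration the length is the forward displacement
  st$ay <- 0
  rec <- stride_length(st, iv)
  expect_equal(rec$length_m, 3, tolerance = 1e-3)
})

test_that("full gait analysis recovers synthetic strides and flags edge cases", {
  expect_equal(nrow(analyze_gait(uniform_stream(300, segment = "left_foot",
                                                az = 1))), 0L)

  tr <- simulate_walk(gait_model_params(n_strides = 5), noise_off())
  g <- analyze_gait(tr$streams$left_foot)
  expect_equal(nrow(g), 5L)
  expect_true(all(diff(g$t_start) > 0))
  expect_lte(sum(g$duration_s), max(tr$streams$left_foot$t))
  expect_true(g$first_stride[1])
  truth <- tr$truth_strides[tr$truth_strides$side == "left", ]
  expect_equal(g$length_m, truth$length_m, tolerance = 0.01)

  ## truncating the trial mid-swing leaves a flagged, excluded final record
  foot <- tr$streams$left_foot
  cut <- g$i_start[5] + 20L
  foot_cut <- imu_stream(as.data.frame(foot)[1:cut, ], "left_foot")
  g2 <- analyze_gait(foot_cut)
  expect_true(g2$end_not_detected[nrow(g2)])
  expect_false(any(g2$end_not_detected[-nrow(g2)]))
  expect_equal(glance(g2)$n_retained, nrow(g2) - 2L)  # first + unterminated
})

test_that("stride length is invariant to sensor yaw misalignment", {
  tr <- walk_zero()
  foot <- tr$streams$left_foot
  base <- analyze_gait(foot)
  keep <- !base$first_stride
  for (phi in c(5, 10, 20) * pi / 180) {
    rot <- foot
    rot$ax <- cos(phi) * foot$ax - sin(phi) * foot$ay
    rot$ay <- sin(phi) * foot$ax + cos(phi) * foot$ay
    g <- analyze_gait(rot)
    expect_equal(nrow(g), nrow(base))
    expect_lt(max(abs(g$length_m[keep] - base$length_m[keep]) /
                    base$length_m[keep]), 0.02)
  }
})

test_that("stride error degrades monotonically with accelerometer noise", {
  mean_err <- vapply(c(0.01, 0.05, 0.15), function(sd) {
    errs <- unlist(lapply(1:5, function(s) {
      tr <- simulate_walk(
        gait_model_params(n_strides = 10),
        sensor_noise_params(accel_white_sd = sd, seed = 1000 + s))
      g <- analyze_gait(tr$streams$left_foot)
      keep <- g[!g$first_stride & !g$end_not_detected, ]
      truth <- tr$truth_strides[tr$truth_strides$side == "left", ]
      m <- merge(keep, truth, by = "stride_index")
      abs(m$length_m.x - m$length_m.y)
    }))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) > 0))
})
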