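test_that("agreement computes RMSE and Pearson correlation with edge cases", {
  x <- c(1, 2, 4, 8)
  expect_equal(agreement(x, x)$rmse, 0)
  expect_equal(agreement(x, x)$cc, 1)
  a <- agreement(x + 3, x)
  expect_equal(a$rmse, 3)
  expect_equal(a$cc, 1)
  z <- x - mean(x)
  expect_equal(agreement(-z, z)$cc, -1)
  expect_true(is.na(agreement(rep(1, 4), x)$cc))

  ## RMSE is translation-sensitive, CC translation/scale-invariant
  withr::with_seed(21, {
    for (i in 1:10) {
      est <- rnorm(50)
      ref <- rnorm(50)
      a0 <- agreement(est, ref)
      a1 <- agreement(2.5 * est + 7, ref)
      expect_false(isTRUE(all.equal(a0$rmse, a1$rmse)))
      expect_equal(a0$cc, a1$cc)
    }
  })
})

test_that("characteristic points land on the generator's analytic extrema", {
  tr <- walk_zero()
  truth <- tidyr::pivot_wider(
    tr$truth_angles[tr$truth_angles$side == "left", ],
    names_from = "joint", values_from = "angle_deg")
  strides <- analyze_gait(tr$streams$left_foot)
  pts <- extract_points(truth, strides)
  expect_true(all(table(pts$stride_index) == 10))

  ## independent recomputation of two unambiguous windowed extrema
  for (k in 3:5) {
    row <- strides[strides$stride_index == k, ]
    swing <- truth$t >= row$t_start & truth$t <= row$t_end
    expect_equal(
      pts$value_deg[pts$stride_index == k &
                      pts$point == "knee_max_flexion_swing"],
      max(truth$knee[swing]))
    expect_equal(
      pts$value_deg[pts$stride_index == k &
                      pts$point == "ankle_max_plantarflexion_swing"],
      min(truth$ankle[swing]))
    ## every located point lies within the stride's cycle
    prow <- pts[pts$stride_index == k & !is.na(pts$t), ]
    nxt <- strides$t_start[strides$stride_index == k + 1]
    hi <- if (length(nxt)) nxt else max(truth$t)
    expect_true(all(prow$t >= row$t_start - 0.1 * row$duration_s &
                      prow$t <= hi))
  }

  ## extrema are at the same sample as on a 10x denser truth grid
  tr_fine <- simulate_walk(gait_model_params(n_strides = 8), noise_off(),
                           rate = 1000)
  tf <- tidyr::pivot_wider(
    tr_fine$truth_angles[tr_fine$truth_angles$side == "left", ],
    names_from = "joint", values_from = "angle_deg")
  row <- strides[strides$stride_index == 4, ]
  fine_sw <- tf$t >= row$t_start & tf$t <= row$t_end
  t_fine <- tf$t[fine_sw][which.max(tf$knee[fine_sw])]
  t_pkg <- pts$t[pts$stride_index == 4 & pts$point == "knee_max_flexion_swing"]
  expect_lt(abs(t_pkg - t_fine), 0.0101)  # within one 100 Hz sample
})

test_that("a single detected stride still yields one row per point", {
  tr <- simulate_walk(gait_model_params(n_strides = 1), noise_off())
  truth <- tidyr::pivot_wider(
    tr$truth_angles[tr$truth_angles$side == "left", ],
    names_from = "joint", values_from = "angle_deg")
  strides <- analyze_gait(tr$streams$left_foot)
  pts <- extract_points(truth, strides)
  expect_equal(length(unique(pts$stride_index)), 1L)
  expect_equal(nrow(pts), 10L)

  ## a stride flagged end_not_detected is excluded
  strides2 <- strides
  strides2$end_not_detected[1] <- TRUE
  expect_equal(nrow(extract_points(truth, strides2)), 0L)
})

test_that("point correlations recover constructed couplings", {
  strides <- tibble::tibble(stride_index = 1:8,
                            velocity_mps = seq(0.8, 1.5, 0.1),
                            length_m = seq(1.1, 1.8, 0.1))
  pts <- tibble::tibble(stride_index = 1:8, point = "hip_max_flexion",
                        value_deg = 20 + 10 * strides$velocity_mps,
                        t = NA_real_, index = NA_integer_)
  r <- correlate_points(pts, strides)
  expect_equal(r$r_velocity, 1, tolerance = 1e-9)
  expect_equal(r$r_length, 1, tolerance = 1e-9)

  withr::with_seed(13, {
    pts$value_deg <- sample(pts$value_deg)
    r <- correlate_points(pts, strides)
    expect_lt(abs(r$r_velocity), 0.9)
  })
  expect_error(correlate_points(pts[1:2, ], strides[1:2, ]), "3 strides")
})

test_that("speed-modulated gait couples hip flexion to stride velocity", {
  ## amplitudes scaled with cadence/speed -> positive correlation
  vals <- lapply(c(0.9, 1.0, 1.1, 1.2), function(f) {
    tr <- simulate_walk(
      gait_model_params(n_strides = 4, stride_length_m = 1.4 * f,
                        cadence_steps_per_min = 110 * f,
                        hip_range = c(-10, 30) * f),
      noise_off())
    truth <- tidyr::pivot_wider(
      tr$truth_angles[tr$truth_angles$side == "left", ],
      names_from = "joint", values_from = "angle_deg")
    strides <- analyze_gait(tr$streams$left_foot)
    pts <- extract_points(truth, strides)
    hf <- pts[pts$point == "hip_max_flexion", ]
    merged <- merge(hf, strides, by = "stride_index")
    merged[, c("value_deg", "velocity_mps")]
  })
  all_pts <- do.call(rbind, vals)
  expect_gt(cor(all_pts$value_deg, all_pts$velocity_mps), 0.9)
})

test_that("tidiers and autoplot methods return the expected shapes", {
  tr <- walk_zero()
  est <- estimate_joint_angle(tr$streams$left_thigh, tr$streams$left_shank,
                              "knee")
  td <- tidy(est)
  expect_setequal(unique(td$estimator), c("gyro", "acc", "kalman"))
  expect_equal(nrow(td), 3 * nrow(est))
  gl <- glance(est)
  expect_equal(gl$joint, "knee")
  expect_s3_class(autoplot(est), "ggplot")

  g <- analyze_gait(tr$streams$left_foot)
  expect_s3_class(autoplot(g), "ggplot")
  expect_s3_class(autoplot(tr), "ggplot")
  expect_equal(glance(g)$n_strides, nrow(g))
})
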