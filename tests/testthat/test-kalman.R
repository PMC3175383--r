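random_psd <- function() {
  A <- matrix(rnorm(4), 2)
  A %*% t(A) + diag(1e-6, 2)
}

test_that("correction obeys the zero-gain and full-trust limits", {
  p <- kalman_params(r_v = 1e12)
  s <- kalman_state(1.5, 0.2, diag(c(2, 1)), p)
  up <- kf_correct(s, dy = 50, p)
  expect_equal(up$d_theta, s$d_theta, tolerance = 1e-6)
  expect_equal(up$d_b, s$d_b, tolerance = 1e-6)

  pinf <- kalman_params(r_v = Inf)
  upinf <- kf_correct(s, dy = 50, pinf)
  expect_identical(upinf$d_theta, s$d_theta)
  expect_identical(upinf$P, s$P)

  p <- kalman_params()
  s <- kalman_state(0, 0, diag(c(1e12, 0)), p)
  up <- kf_correct(s, dy = 7, p)
  expect_equal(up$d_theta, 7, tolerance = 1e-3)

  expect_error(kf_correct(kalman_state(0, 0, diag(c(-1, 1)), p), 0, p),
               "non-PSD")
})

test_that("prediction propagates mean and covariance per the transition model", {
  p <- kalman_params(dt = 0.01)
  s <- kf_predict(kalman_state(2, 0.1, params = p), p)
  expect_equal(s$d_theta, 2.001)
  expect_equal(s$d_b, 0.1)

  ## with negligible process noise, P_pred = F F' computed by hand
  p0 <- kalman_params(q_w = 1e-300, dt = 0.5)
  s <- kf_predict(kalman_state(0, 0, diag(2), p0), p0)
  expect_equal(s$P, matrix(c(1.25, 0.5, 0.5, 1), 2), tolerance = 1e-12)
  expect_equal(kf_predict(kalman_state(0, 0, params = p), p)$d_theta, 0)
})

test_that("recursion matches an independently coded closed form over 1000 steps", {
  ## textbook 2-state closed form, written from scratch (simple-form update)
  withr::with_seed(11, {
    p <- kalman_params(q_w = 1e-4, r_v = 0.5, dt = 0.01)
    m <- c(0.3, -0.1)
    P <- random_psd()
    state <- kalman_state(m[1], m[2], P, p)
    Fm <- matrix(c(1, 0, p$dt, 1), 2)
    Q <- p$q_w * matrix(1, 2, 2)
    H <- matrix(c(1, 0), 1)
    for (i in 1:1000) {
      dy <- rnorm(1, sd = 3)
      ## oracle
      S <- as.numeric(H %*% P %*% t(H)) + p$r_v
      K <- (P %*% t(H)) / S
      m <- m + as.numeric(K) * (dy - m[1])
      P <- (diag(2) - K %*% H) %*% P
      m <- as.numeric(Fm %*% m)
      P <- Fm %*% P %*% t(Fm) + Q
      ## implementation
      state <- kf_predict(kf_correct(state, dy, p), p)
      expect_lt(abs(state$d_theta - m[1]), 1e-9)
      expect_lt(abs(state$d_b - m[2]), 1e-9)
      expect_lt(max(abs(state$P - (P + t(P)) / 2)), 1e-9)
    }
  })
})

test_that("covariance stays symmetric PSD over 10^4 steps", {
  withr::with_seed(3, {
    p <- kalman_params()
    run <- NULL
    state <- kalman_state(params = p)
    for (k in 1:10000) {
      state <- kf_predict(kf_correct(state, rnorm(1, sd = 10), p), p)
      if (k %% 250 == 0) {
        expect_equal(state$P, t(state$P))
        expect_gte(min(eigen(state$P, symmetric = TRUE,
                             only.values = TRUE)$values), -1e-9)
      }
    }
  })
})

test_that("r_v = Inf degrades the pipeline to pure gyro integration exactly", {
  tr <- walk_zero()
  est <- estimate_joint_angle(tr$streams$left_thigh, tr$streams$left_shank,
                              "knee", kalman_params(r_v = Inf))
  expect_identical(est$theta_hat, est$theta_gyro)
  expect_identical(est$d_theta, rep(0, nrow(est)))
})

test_that("constant gyro bias is rejected and the bound shrinks with r_v", {
  tr <- simulate_walk(gait_model_params(n_strides = 50), noise_off())
  distal <- tr$streams$left_shank
  distal$wy <- distal$wy + 1  # +1 deg/s offset drift on one gyro
  truth <- tr$truth_angles[tr$truth_angles$side == "left" &
                             tr$truth_angles$joint == "knee", ]$angle_deg
  est <- estimate_joint_angle(tr$streams$left_thigh, distal, "knee")
  n <- nrow(est)
  raw_err <- abs(est$theta_gyro - truth)
  expect_gt(raw_err[n], 0.9 * est$t[n])  # grows ~ t deg
  expect_lt(max(abs(est$theta_hat - truth)), 5)

  ## trusting the accelerometer more (smaller r_v) tightens the drift
  ## bound; checked on a static pose where the discrepancy is pure drift
  sp <- uniform_stream(3000, ax = 0.2, az = -sqrt(0.96))
  sd_ <- uniform_stream(3000, segment = "left_shank", ax = 0.2,
                        az = -sqrt(0.96), wy = 1)
  bounds <- vapply(c(100, 1, 0.01), function(rv) {
    e <- estimate_joint_angle(sp, sd_, "knee", kalman_params(r_v = rv))
    max(abs(e$theta_hat))
  }, numeric(1))
  expect_true(all(diff(bounds) < 0))
})

test_that("identical streams give a constant joint angle up to the transient", {
  st <- uniform_stream(600, ax = 0.2, az = -sqrt(1 - 0.04),
                       wy = 5 * sin((0:599) / 20))
  st2 <- st
  attr(st2, "segment") <- "left_shank"
  est <- estimate_joint_angle(st, st2, "knee")
  expect_lt(max(abs(est$theta_hat - est$theta_hat[1])), 1e-6)
  expect_error(estimate_joint_angle(st, uniform_stream(10), "knee"),
               "grids mismatch")
})

test_that("Kalman correction beats raw integration under default drift", {
  ## RMSE(kalman) < RMSE(gyro) and CC(kalman) > CC(gyro) on a long noisy walk
  tr <- simulate_walk(gait_model_params(n_strides = 60),
                      sensor_noise_params(seed = 5))
  truth <- tr$truth_angles[tr$truth_angles$side == "left" &
                             tr$truth_angles$joint == "knee", ]$angle_deg
  est <- estimate_joint_angle(tr$streams$left_thigh, tr$streams$left_shank,
                              "knee")
  a_kal <- agreement(est$theta_hat, truth)
  a_raw <- agreement(est$theta_gyro, truth)
  expect_lt(a_kal$rmse, a_raw$rmse)
  expect_gt(a_kal$cc, a_raw$cc)
})
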