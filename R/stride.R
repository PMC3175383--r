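#' Stationary-state detection parameters
#'
#' Foot movement is detected from the sum over the three accelerometer axes
#' of the absolute deviation from the resting gravity baseline. A step begins
#' when that sum exceeds `accel_thresh_G` for `start_consecutive` successive
#' samples, and ends at the first sub-threshold sample of the first
#' forward-looking window of `end_window` samples containing at least
#' `end_hits` sub-threshold samples.
#'
#' @param accel_thresh_G Threshold in G (default 0.15).
#' @param start_consecutive Consecutive supra-threshold samples starting a
#'   step (default 3).
#' @param end_hits Sub-threshold samples required within the end window
#'   (default 3).
#' @param end_window Length of the forward-looking end window in samples
#'   (default 10).
#' @param rest_window_s Initial rest interval, in seconds, used to estimate
#'   the per-axis gravity baseline (default 0.5).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(accel_thresh_G = 0.15, start_consecutive = 3L,
                             end_hits = 3L, end_window = 10L,
                             rest_window_s = 0.5) {
  stopifnot(accel_thresh_G > 0, start_consecutive > 0, end_hits > 0,
            end_window > 0, end_hits <= end_window, rest_window_s > 0)
  structure(list(accel_thresh_G = accel_thresh_G,
                 start_consecutive = as.integer(start_consecutive),
                 end_hits = as.integer(end_hits),
                 end_window = as.integer(end_window),
                 rest_window_s = rest_window_s),
            class = "detection_params")
}

rest_baseline <- function(stream, idx) {
  vapply(c("ax", "ay", "az"), function(ch) stats::median(stream[[ch]][idx]),
         numeric(1))
}

#' Movement scalar from a foot accelerometer
#'
#' Per-sample sum over the three axes of the absolute deviation of
#' acceleration from the resting gravity baseline, in G. At rest the signal
#' is the sensor noise floor; during swing it rises well above the detection
#' threshold. The baseline defaults to the per-axis median over the first
#' `rest_window_s` seconds (the trial is assumed to start at rest); pass
#' `baseline` to use a refined estimate, e.g. medians over all detected rest
#' samples.
#'
#' @param stream Foot [imu_stream()] with all three accelerometer axes.
#' @param params A [detection_params()].
#' @param baseline Optional named vector `c(ax=, ay=, az=)` of baseline
#'   accelerations in G.
#' @return Tibble with columns `t`, `s` (G).
#' @export
movement_signal <- function(stream, params = detection_params(),
                            baseline = NULL) {
  if (is.null(baseline)) {
    idx <- which(stream$t <= stream$t[1] + params$rest_window_s)
    baseline <- rest_baseline(stream, idx)
  }
  s <- abs(stream$ax - baseline[["ax"]]) +
    abs(stream$ay - baseline[["ay"]]) +
    abs(stream$az - baseline[["az"]])
  tibble(t = stream$t, s = s)
}

#' Detect movement intervals from the movement scalar
#'
#' @param s Numeric vector (movement scalar in G) or the tibble returned by
#'   [movement_signal()].
#' @param params A [detection_params()].
#' @param t Optional time stamps (taken from `s` when it is a tibble).
#' @return Tibble with one row per interval: `i_start`, `i_end` (1-based
#'   sample indices; `i_end` is the first stationary sample), `t_start`,
#'   `t_end`, `end_detected`. A trailing movement without a detected end is
#'   returned with `end_detected = FALSE` and `i_end = NA`.
#' @export
detect_steps <- function(s, params = detection_params(), t = NULL) {
  if (is.data.frame(s)) {
    t <- s$t
    s <- s$s
  }
  n <- length(s)
  if (is.null(t)) t <- seq_len(n)
  th <- params$accel_thresh_G
  nc <- params$start_consecutive
  hi <- s > th
  out <- list()
  k <- 1L
  while (k <= n - nc + 1L) {
    ## onset: first run of nc consecutive supra-threshold samples
    onset <- NA_integer_
    for (j in k:(n - nc + 1L)) {
      if (all(hi[j:(j + nc - 1L)])) {
        onset <- j
        break
      }
    }
    if (is.na(onset)) break
    ## offset: scan forward-looking windows after the onset
    offset <- NA_integer_
    j <- onset + 1L
    while (j + params$end_window - 1L <= n) {
      win <- j:(j + params$end_window - 1L)
      low <- win[!hi[win]]
      if (length(low) >= params$end_hits) {
        offset <- low[1]
        break
      }
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- tibble(
      i_start = onset, i_end = offset,
      t_start = t[onset], t_end = if (is.na(offset)) NA_real_ else t[offset],
      end_detected = !is.na(offset)
    )
    if (is.na(offset)) break
    k <- offset + 1L
  }
  if (!length(out)) {
    return(tibble(i_start = integer(), i_end = integer(),
                  t_start = numeric(), t_end = numeric(),
                  end_detected = logical()))
  }
  dplyr::bind_rows(out)
}

#' Tilt-compensated horizontal foot velocity over a movement interval
#'
#' The foot pitch from gyro integration (seeded with the pre-movement
#' accelerometer tilt) rotates the measured specific force into the world
#' frame; the geometry `ax*cos(theta) - az*sin(theta)` recovers the
#' horizontal acceleration with the gravity component cancelling exactly.
#' Integration starts from zero velocity, which holds by construction
#' because the interval begins at the stationary foot-flat state.
#'
#' @param stream Foot [imu_stream()].
#' @param interval One row of [detect_steps()] output (with a detected end).
#' @param theta_init Initial foot tilt in degrees (see
#'   [foot_initial_tilt()]).
#' @return Tibble `t`, `v` (m/s) over `i_start:i_end`.
#' @export
horizontal_velocity <- function(stream, interval, theta_init = 0) {
  idx <- interval$i_start:interval$i_end
  if (length(idx) < 3) abort("interval shorter than 3 samples")
  t <- stream$t[idx]
  th <- integrate_gyro(t, stream$wy[idx], theta_init)$theta_g * pi / 180
  ah <- (stream$ax[idx] * cos(th) - stream$az[idx] * sin(th)) * G_MS2
  tibble(t = t, v = as.numeric(pracma::cumtrapz(t, ah)))
}

#' Linear zero-velocity (ZUPT) correction
#'
#' The foot is stationary at both ends of a movement interval, so any
#' residual terminal velocity is integration drift. It is removed by a
#' linear-in-time correction: `v_c(t) = v(t) - (t/T) v(T)`, which is exact
#' for drift caused by a constant acceleration error and leaves the
#' corrected velocity exactly zero at both ends.
#'
#' @param v Velocity series (numeric, starting at 0), or the tibble from
#'   [horizontal_velocity()].
#' @param t Time stamps (taken from `v` when it is a tibble).
#' @return Corrected series in the same form as the input.
#' @export
zupt_linear_correction <- function(v, t = NULL) {
  tib <- is.data.frame(v)
  if (tib) {
    t <- v$t
    vv <- v$v
  } else {
    vv <- v
    if (is.null(t)) t <- seq_along(vv) - 1
  }
  T_ <- t[length(t)] - t[1]
  if (T_ <= 0) abort("interval duration must be positive")
  vc <- vv - (t - t[1]) / T_ * vv[length(vv)]
  if (tib) tibble(t = t, v = vc) else vc
}

#' Stride length, duration and velocity for one movement interval
#'
#' Forward displacement is the integral of the ZUPT-corrected horizontal
#' velocity. Misalignment of the sensor x-axis with the travel direction is
#' corrected by building the lateral velocity the same way from the y-axis
#' acceleration (baseline-removed, same linear correction) and taking the
#' Euclidean norm of the two displacements.
#'
#' @param stream Foot [imu_stream()].
#' @param interval One row of [detect_steps()] output.
#' @param params A [detection_params()].
#' @param baseline Optional gravity baseline as in [movement_signal()].
#' @return One-row tibble: `t_start`, `t_end`, `duration_s`, `length_m`,
#'   `velocity_mps`, `theta_init_deg`, `first_stride`, `clamped_tilt`,
#'   `end_not_detected`.
#' @export
stride_length <- function(stream, interval, params = detection_params(),
                          baseline = NULL) {
  if (is.null(baseline)) {
    idx0 <- which(stream$t <= stream$t[1] + params$rest_window_s)
    baseline <- rest_baseline(stream, idx0)
  }
  if (!isTRUE(interval$end_detected)) {
    return(tibble(t_start = interval$t_start, t_end = NA_real_,
                  duration_s = NA_real_, length_m = NA_real_,
                  velocity_mps = NA_real_, theta_init_deg = NA_real_,
                  first_stride = FALSE, clamped_tilt = FALSE,
                  end_not_detected = TRUE))
  }
  ## initial tilt from the six rest samples immediately before the onset
  ti_start <- interval$i_start - 6L
  first_stride <- FALSE
  if (ti_start < 1L) {
    ti_start <- 1L
    first_stride <- TRUE
  }
  theta_init <- foot_initial_tilt(stream, ti_start)
  idx <- interval$i_start:interval$i_end
  t <- stream$t[idx]
  T_ <- t[length(t)] - t[1]

  vh <- zupt_linear_correction(horizontal_velocity(stream, interval,
                                                   as.numeric(theta_init)))
  dx <- pracma::trapz(vh$t, vh$v)
  ay <- (stream$ay[idx] - baseline[["ay"]]) * G_MS2
  vy <- zupt_linear_correction(as.numeric(pracma::cumtrapz(t, ay)), t)
  dy <- pracma::trapz(t, vy)

  L <- sqrt(dx^2 + dy^2)
  tibble(t_start = t[1], t_end = t[length(t)], duration_s = T_,
         length_m = L, velocity_mps = L / T_,
         theta_init_deg = as.numeric(theta_init),
         first_stride = first_stride,
         clamped_tilt = isTRUE(attr(theta_init, "clamped")),
         end_not_detected = FALSE)
}

#' Full per-stride gait analysis of a foot stream
#'
#' Segments the trial into movement intervals by stationary-state detection
#' (two passes: the gravity baseline is re-estimated from all detected rest
#' samples after a first pass) and estimates length, duration, and velocity
#' for each stride. The first stride is flagged; a trailing movement whose
#' end is never detected is kept with `end_not_detected = TRUE` so callers
#' can exclude it from summaries.
#'
#' @param foot_stream Foot [imu_stream()] on a uniform grid.
#' @param params A [detection_params()].
#' @return A tibble of class `stride_table`, one row per detected stride,
#'   with a `stride_index` column plus the columns of [stride_length()] and
#'   the interval indices.
#' @export
analyze_gait <- function(foot_stream, params = detection_params()) {
  empty <- tibble(stride_index = integer(), i_start = integer(),
                  i_end = integer(), t_start = numeric(), t_end = numeric(),
                  duration_s = numeric(), length_m = numeric(),
                  velocity_mps = numeric(), theta_init_deg = numeric(),
                  first_stride = logical(), clamped_tilt = logical(),
                  end_not_detected = logical())
  bl <- NULL
  sig <- movement_signal(foot_stream, params)
  steps <- detect_steps(sig, params)
  if (nrow(steps)) {
    ## refine the gravity baseline using every detected rest sample
    rest <- rep(TRUE, nrow(foot_stream))
    for (i in seq_len(nrow(steps))) {
      iend <- if (is.na(steps$i_end[i])) nrow(foot_stream) else steps$i_end[i]
      rest[steps$i_start[i]:iend] <- FALSE
    }
    if (any(rest)) {
      bl <- rest_baseline(foot_stream, which(rest))
      steps <- detect_steps(movement_signal(foot_stream, params, bl), params)
    }
  }
  if (!nrow(steps)) {
    return(tibble::new_tibble(empty, class = "stride_table"))
  }
  recs <- purrr::map(seq_len(nrow(steps)), function(i) {
    r <- stride_length(foot_stream, steps[i, ], params, baseline = bl)
    dplyr::bind_cols(tibble(stride_index = i, i_start = steps$i_start[i],
                            i_end = steps$i_end[i]), r)
  })
  out <- dplyr::bind_rows(recs)
  out$first_stride[1] <- TRUE
  tibble::new_tibble(out, class = "stride_table")
}

#' @export
print.stride_table <- function(x, ...) {
  cat(sprintf("<stride_table: %d strides>\n", nrow(x)))
  NextMethod()
}
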