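#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a joint-angle series
#'
#' Long format: one row per sample and estimator (`gyro`, `acc`, `kalman`),
#' with the joint and side carried as columns.
#'
#' @param x A `joint_angle_series`.
#' @param ... Unused.
#' @return A tibble `t`, `joint`, `side`, `estimator`, `angle_deg`.
#' @export
tidy.joint_angle_series <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x)[, c("t", "theta_gyro", "theta_acc", "theta_hat")],
    -"t", names_to = "estimator", values_to = "angle_deg")
  long$estimator <- c(theta_gyro = "gyro", theta_acc = "acc",
                      theta_hat = "kalman")[long$estimator]
  dplyr::mutate(long, joint = attr(x, "joint"), side = attr(x, "side"),
                .after = "t")
}

#' One-row summary of a joint-angle series
#'
#' @param x A `joint_angle_series`.
#' @param ... Unused.
#' @return Tibble with `joint`, `side`, `n`, `duration_s`, the final
#'   drift-error and bias-increment estimates, and the RMS gyro/accelerometer
#'   discrepancy.
#' @export
glance.joint_angle_series <- function(x, ...) {
  tibble(joint = attr(x, "joint"), side = attr(x, "side"), n = nrow(x),
         duration_s = x$t[nrow(x)] - x$t[1],
         final_d_theta_deg = x$d_theta[nrow(x)],
         final_d_b_deg = x$d_b[nrow(x)],
         rms_correction_deg = sqrt(mean(x$d_theta^2)))
}

#' Tidy a stride table
#' @param x A `stride_table`.
#' @param ... Unused.
#' @return The per-stride tibble, strides without a detected end removed.
#' @export
tidy.stride_table <- function(x, ...) {
  dplyr::filter(as_tibble(x), !.data$end_not_detected)
}

#' One-row gait summary from a stride table
#'
#' Summary statistics exclude the first stride and strides whose end was
#' not detected.
#'
#' @param x A `stride_table`.
#' @param ... Unused.
#' @return Tibble: `n_strides`, `n_retained`, mean/SD length, mean
#'   duration, mean velocity, cadence (strides per minute of one foot).
#' @export
glance.stride_table <- function(x, ...) {
  keep <- dplyr::filter(as_tibble(x), !.data$end_not_detected,
                        !.data$first_stride)
  tibble(n_strides = nrow(x), n_retained = nrow(keep),
         mean_length_m = mean(keep$length_m),
         sd_length_m = stats::sd(keep$length_m),
         mean_duration_s = mean(keep$duration_s),
         mean_velocity_mps = mean(keep$velocity_mps),
         cadence_strides_per_min = if (nrow(keep) > 1) {
           60 * (nrow(keep) - 1) /
             (keep$t_start[nrow(keep)] - keep$t_start[1])
         } else NA_real_)
}
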