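#' Plot a joint-angle series
#'
#' Overlays the raw gyro-integrated angle, the low-passed accelerometer
#' angle, and the Kalman-corrected estimate. With drifting gyros the gyro
#' trace walks away while the corrected trace stays on the gait curve.
#'
#' @param object A `joint_angle_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.joint_angle_series <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$t, y = .data$angle_deg,
                               colour = .data$estimator)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "angle (deg)",
                  title = sprintf("%s (%s)", attr(object, "joint"),
                                  attr(object, "side") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a stride table
#'
#' Stride length against stride onset time; excluded strides (first, end
#' not detected) are hollow.
#'
#' @param object A `stride_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stride_table <- function(object, ...) {
  d <- as_tibble(object)
  d$excluded <- d$first_stride | d$end_not_detected
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_start, y = .data$length_m,
                                  shape = .data$excluded)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "stride onset (s)", y = "stride length (m)") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic trial's ground-truth angles
#'
#' @param object A `synthetic_trial`.
#' @param ... Unused.
#' @return A ggplot faceted by joint.
#' @export
autoplot.synthetic_trial <- function(object, ...) {
  ggplot2::ggplot(object$truth_angles,
                  ggplot2::aes(x = .data$t, y = .data$angle_deg,
                               colour = .data$side)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~joint, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
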