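#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

## Standard gravity used for all G <-> m/s^2 conversions.
G_MS2 <- 9.80665

SEGMENTS <- c(
  "left_foot", "right_foot", "left_shank", "right_shank",
  "left_thigh", "right_thigh", "lumbar"
)

IMU_CHANNELS <- c("ax", "ay", "az", "wx", "wy", "wz")

#' Construct an IMU stream
#'
#' An `imu_stream` is a tibble of time-stamped inertial samples from one
#' body-worn sensor, in the package's canonical segment frame: `x` anterior,
#' `y` medio-lateral, `z` longitudinal (pointing down the segment when
#' standing) for limb and lumbar sensors; for the foot sensor `x` is anterior
#' along the foot and `z` is dorsal (up when the foot is flat). Accelerations
#' are specific force in units of G; angular velocities are in deg/s about the
#' segment axes (`wy` is the sagittal-plane pitch rate). Axes the physical
#' sensor does not provide are `NA`, never zero.
#'
#' @param data Data frame with column `t` (seconds, strictly increasing) and
#'   any of `ax`, `ay`, `az` (G), `wx`, `wy`, `wz` (deg/s).
#' @param segment One of `"left_foot"`, `"right_foot"`, `"left_shank"`,
#'   `"right_shank"`, `"left_thigh"`, `"right_thigh"`, `"lumbar"`.
#' @param nominal_rate Nominal sampling rate in Hz (default 100).
#' @param check If `TRUE` (default) validate invariants: finite non-negative
#'   strictly increasing timestamps, |acceleration| < 16 G, finite rates, and
#'   median sampling interval within 20% of `1/nominal_rate`.
#' @return A tibble of class `imu_stream` with attributes `segment` and
#'   `nominal_rate`.
#' @export
#' @examples
#' imu_stream(data.frame(t = (0:9) / 100, ax = 0, ay = 0, az = -1, wy = 0),
#'            segment = "left_thigh")
imu_stream <- function(data, segment, nominal_rate = 100, check = TRUE) {
  segment <- match.arg(segment, SEGMENTS)
  data <- as_tibble(data)
  if (!"t" %in% names(data)) abort("`data` must have a `t` column (seconds)")
  extra <- setdiff(names(data), c("t", IMU_CHANNELS))
  if (length(extra)) abort(paste0("unknown channel name: ", extra[1]))
  for (ch in setdiff(IMU_CHANNELS, names(data))) data[[ch]] <- NA_real_
  data <- data[, c("t", IMU_CHANNELS)]
  data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), as.numeric))
  out <- tibble::new_tibble(data, segment = segment,
                            nominal_rate = as.numeric(nominal_rate),
                            class = "imu_stream")
  if (check) validate_imu_stream(out)
  out
}

validate_imu_stream <- function(x) {
  t <- x$t
  if (anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("timestamps must be finite and non-negative")
  }
  if (length(t) > 1) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      abort(sprintf("non-monotone at row %d", bad[1] + 1L))
    }
    dt_med <- stats::median(diff(t))
    rate <- attr(x, "nominal_rate")
    if (abs(dt_med - 1 / rate) > 0.2 / rate) {
      abort(sprintf(
        "median sampling interval %.4g s is not within 20%% of 1/%g s",
        dt_med, rate
      ))
    }
  }
  for (ch in c("ax", "ay", "az")) {
    v <- x[[ch]]
    if (any(abs(v) >= 16, na.rm = TRUE)) {
      abort(sprintf("|%s| exceeds the 16 G sensor sanity bound", ch))
    }
  }
  for (ch in c("wx", "wy", "wz")) {
    v <- x[[ch]]
    if (any(!is.finite(v[!is.na(v)]))) abort(sprintf("%s must be finite", ch))
  }
  invisible(x)
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream: %s, %d samples @ %g Hz nominal>\n",
              attr(x, "segment"), nrow(x), attr(x, "nominal_rate")))
  NextMethod()
}

seg_attr <- function(x) attr(x, "segment") %||% "unknown"

stream_dt <- function(x) 1 / (attr(x, "nominal_rate") %||% 100)

## Check two streams share a sampling grid.
same_grid <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) && all(abs(a$t - b$t) < tol)
}
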