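#' Tilt angle of the gravity vector in the sagittal plane
#'
#' Quadrant-correct (two-argument arctangent) angle of the measured gravity
#' vector `(ax, az)` from the x-axis, in degrees, range (-180, 180]. The
#' result depends only on the direction of the vector, not its magnitude, so
#' any accelerometer scale error cancels. Both components near zero means the
#' sensor is in free fall and tilt is unobservable.
#'
#' @param ax_g,az_g Gravity components along the two in-plane axes, in G.
#'   Vectorized.
#' @return Angle(s) in degrees.
#' @export
#' @examples
#' tilt_from_gravity(1, 0)                 # 0
#' tilt_from_gravity(sqrt(2)/2, sqrt(2)/2) # 45
tilt_from_gravity <- function(ax_g, az_g) {
  if (any(abs(ax_g) < 1e-6 & abs(az_g) < 1e-6)) {
    abort("free-fall / unobservable tilt: both gravity components < 1e-6 G")
  }
  atan2(az_g, ax_g) * 180 / pi
}

## Segment tilt from specific-force components in the canonical segment frame.
## Limb/lumbar sensors (z down the segment): standing gives (ax, az) = (0, -1),
## forward tilt theta gives (sin theta, -cos theta). Foot sensors (z dorsal):
## flat gives (0, +1), toe-up pitch theta gives (sin theta, cos theta).
segment_tilt <- function(ax_g, az_g, segment) {
  if (grepl("foot", segment)) tilt_from_gravity(az_g, ax_g)
  else tilt_from_gravity(-az_g, ax_g)
}

## Causal 2nd-order Butterworth low-pass with DC-steady-state start-up:
## the input is padded with its first value long enough for the transient to
## decay below double precision noise, so a constant signal passes unchanged
## from sample one.
butter_lowpass <- function(x, cutoff, rate) {
  if (cutoff >= rate / 2) {
    abort(sprintf("cutoff %g Hz must be below the Nyquist frequency %g Hz",
                  cutoff, rate / 2))
  }
  flt <- signal::butter(2, cutoff / (rate / 2), type = "low")
  npad <- ceiling(12 * rate / cutoff)
  y <- signal::filter(flt, c(rep(x[1], npad), x))
  as.numeric(y)[-seq_len(npad)]
}

#' Low-pass filter accelerometer channels toward the gravity component
#'
#' Applies a causal 2nd-order Butterworth low-pass (default cut-off 0.5 Hz)
#' to each acceleration channel of a uniformly sampled stream, attenuating
#' movement acceleration so that what remains approximates the gravity
#' vector. DC gain is exactly 1. Gyroscope channels pass through untouched.
#'
#' @param stream An [imu_stream()] on a uniform grid.
#' @param cutoff Cut-off frequency in Hz (default 0.5). Must be below Nyquist.
#' @return An [imu_stream()] with filtered `ax`, `ay`, `az`.
#' @export
lowpass_gravity <- function(stream, cutoff = 0.5) {
  rate <- attr(stream, "nominal_rate")
  out <- as_tibble(stream)
  for (ch in c("ax", "ay", "az")) {
    if (!all(is.na(out[[ch]]))) {
      out[[ch]] <- butter_lowpass(out[[ch]], cutoff, rate)
    }
  }
  imu_stream(out, segment = seg_attr(stream), nominal_rate = rate,
             check = FALSE)
}

#' Initial foot tilt from six accelerometer samples
#'
#' During quiet stance the anterior acceleration component is `sin(theta)` G,
#' so the foot pitch is recovered as `arcsin(ax)`, averaged over six
#' consecutive samples to suppress noise. Samples with |ax| > 1 G indicate
#' movement contamination; they are clamped to +/-1 and the result is flagged.
#'
#' @param stream Foot [imu_stream()].
#' @param start_index 1-based index of the first of the six samples.
#' @return Tilt in degrees, with attribute `clamped` (logical).
#' @export
foot_initial_tilt <- function(stream, start_index = 1L) {
  idx <- start_index + 0:5
  if (start_index < 1 || max(idx) > nrow(stream)) {
    abort("six samples are required at `start_index`")
  }
  ax <- stream$ax[idx]
  clamped <- any(abs(ax) > 1)
  ax <- pmin(pmax(ax, -1), 1)
  structure(mean(asin(ax)) * 180 / pi, clamped = clamped)
}

#' Integrate angular velocity into an angle series
#'
#' Cumulative trapezoidal integration of a sagittal angular-velocity series
#' plus the initial angle. This is the raw gyroscope angle; uncorrected, any
#' offset drift in the rate accumulates linearly here.
#'
#' @param t Time stamps in seconds (uniform grid).
#' @param omega Angular velocity in deg/s.
#' @param theta0 Initial angle in deg.
#' @return Tibble with columns `t`, `theta_g` (deg) and attribute `theta0`;
#'   `theta_g[1] == theta0`.
#' @export
integrate_gyro <- function(t, omega, theta0 = 0) {
  stopifnot(length(t) == length(omega), length(t) >= 1)
  theta <- theta0 + as.numeric(pracma::cumtrapz(t, omega))
  tibble::new_tibble(tibble(t = t, theta_g = theta), theta0 = theta0,
                     class = "gyro_angle_series")
}
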