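#' Sensor placement configuration
#'
#' Declares, per segment, how the physical sensor axes map onto the canonical
#' segment frame (x anterior, y medio-lateral, z longitudinal-down for limb
#' segments; x anterior, z dorsal for the foot) and the gravity constant used
#' for G conversions. Each mapping is a signed permutation such as
#' `c(x = "+y", y = "-x", z = "+z")`, read "canonical x is sensor +y, ...".
#' Sensors with fewer than three gyroscope axes simply leave the absent
#' channels out of their CSV files; the mapping then carries them as `NA`.
#'
#' @param maps Named list of per-segment axis mappings. Segments not named use
#'   the identity mapping.
#' @param g Gravity constant in m/s^2 used to convert G to SI (default
#'   standard gravity, 9.80665).
#' @return An object of class `placement_config`.
#' @export
#' @examples
#' placement_config(list(left_foot = c(x = "+y", y = "-x", z = "+z")))
placement_config <- function(maps = list(), g = 9.80665) {
  stopifnot(is.list(maps), is.numeric(g), g > 0)
  if (length(maps) && is.null(names(maps))) abort("`maps` must be named by segment")
  maps <- lapply(maps, check_axis_map)
  bad <- setdiff(names(maps), SEGMENTS)
  if (length(bad)) abort(paste0("unknown segment in placement config: ", bad[1]))
  structure(list(maps = maps, g = g), class = "placement_config")
}

check_axis_map <- function(map) {
  map <- unlist(map)
  if (!setequal(names(map), c("x", "y", "z"))) {
    abort("axis map must name exactly x, y, z")
  }
  map <- map[c("x", "y", "z")]
  ok <- grepl("^[+-][xyz]$", map)
  if (!all(ok)) abort("axis map entries must look like '+x', '-y', ...")
  if (anyDuplicated(substr(map, 2, 2))) {
    abort("axis map must be a signed permutation (each sensor axis used once)")
  }
  ## right-handedness: determinant of the signed permutation matrix must be +1
  m <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (i in seq_len(3)) {
    m[i, substr(map[i], 2, 2)] <- if (substr(map[i], 1, 1) == "+") 1 else -1
  }
  if (det(m) < 0) abort("axis map must be right-handed (determinant +1)")
  map
}

#' Read a placement configuration from YAML
#'
#' @param path YAML file with optional top-level `g` and a `segments` block
#'   mapping segment names to `{x: "+y", y: "-x", z: "+z"}` entries.
#' @return A [placement_config()].
#' @export
read_placement_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  maps <- lapply(y$segments %||% list(), function(m) {
    ## YAML 1.1 reads a bare `y`/`n` key as a boolean; map it back
    names(m)[names(m) == "TRUE"] <- "y"
    names(m)[names(m) == "FALSE"] <- "n"
    m
  })
  placement_config(maps = maps, g = y$g %||% 9.80665)
}

apply_axis_map <- function(data, map) {
  if (is.null(map)) return(data)
  out <- data
  for (triple in list(c("ax", "ay", "az"), c("wx", "wy", "wz"))) {
    src <- data[triple]
    for (i in seq_len(3)) {
      from <- paste0(substr(triple[1], 1, 1), substr(map[i], 2, 2))
      sgn <- if (substr(map[i], 1, 1) == "+") 1 else -1
      out[[triple[i]]] <- sgn * data[[from]]
    }
  }
  out
}

#' Read an IMU CSV file
#'
#' Reads one sensor's time series from a comma-separated file with a header
#' naming `t` and the available channels (`ax,ay,az` in G, `wx,wy,wz` in
#' deg/s), remaps the axes into the canonical segment frame, and validates the
#' stream. Files with non-monotone timestamps, unknown channel names, or more
#' than 5% missing samples are rejected.
#'
#' @param path CSV file path.
#' @param segment Segment the sensor is attached to (see [imu_stream()]).
#' @param placement Optional [placement_config()]; identity mapping if absent.
#' @param nominal_rate Nominal sampling rate in Hz.
#' @return An [imu_stream()].
#' @export
read_imu_csv <- function(path, segment, placement = NULL, nominal_rate = 100) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  extra <- setdiff(names(raw), c("t", IMU_CHANNELS))
  if (length(extra)) abort(paste0("unknown channel name: ", extra[1]))
  if (!"t" %in% names(raw)) abort("CSV must have a `t` column")
  present <- intersect(IMU_CHANNELS, names(raw))
  if (length(present)) {
    miss <- mean(rowSums(is.na(raw[present])) > 0)
    if (miss > 0.05) {
      abort(sprintf("%.1f%% of samples have missing values (> 5%%)", 100 * miss))
    }
  }
  for (ch in setdiff(IMU_CHANNELS, names(raw))) raw[[ch]] <- NA_real_
  map <- if (!is.null(placement)) placement$maps[[segment]] else NULL
  raw <- apply_axis_map(raw[, c("t", IMU_CHANNELS)], map)
  imu_stream(raw, segment = segment, nominal_rate = nominal_rate)
}

#' Write an IMU stream to CSV
#'
#' Channels that are entirely absent (`NA`) are omitted from the file. Values
#' are serialized at full (shortest round-trip) precision, so
#' `read_imu_csv()` recovers them exactly.
#'
#' @param stream An [imu_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  keep <- c("t", IMU_CHANNELS[vapply(IMU_CHANNELS,
                                     function(ch) !all(is.na(stream[[ch]])),
                                     logical(1))])
  readr::write_csv(as_tibble(stream)[, keep, drop = FALSE], path,
                   progress = FALSE)
  invisible(path)
}

#' Resample an IMU stream onto a uniform grid
#'
#' Wireless sensors time-stamp each sample with their own clock; small
#' sampling-interval jitter degrades every fixed-step integral downstream.
#' This linearly interpolates all channels onto the uniform
#' `1/nominal_rate` grid spanning `[t0, tN]`, so the filters can treat the
#' sampling interval as an exact constant.
#'
#' @param stream An [imu_stream()].
#' @return An [imu_stream()] on a uniform grid.
#' @export
regularize_timestamps <- function(stream) {
  t <- stream$t
  dt <- stream_dt(stream)
  gaps <- diff(t)
  bad <- which(gaps > 5 * dt)
  if (length(bad)) {
    abort(sprintf("gap of %.4g s between t = %.4g and t = %.4g (rows %d-%d)",
                  gaps[bad[1]], t[bad[1]], t[bad[1] + 1], bad[1], bad[1] + 1L))
  }
  grid <- seq(t[1], t[length(t)], by = dt)
  out <- tibble(t = grid)
  for (ch in IMU_CHANNELS) {
    v <- stream[[ch]]
    out[[ch]] <- if (all(is.na(v))) NA_real_ else {
      stats::approx(t, v, xout = grid, rule = 2)$y
    }
  }
  imu_stream(out, segment = seg_attr(stream),
             nominal_rate = attr(stream, "nominal_rate"))
}
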