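#' Agreement between an estimated and a reference series
#'
#' Root-mean-square error and Pearson correlation on a common grid. RMSE is
#' sensitive to offsets; the correlation is translation- and
#' scale-invariant. If either series is constant the correlation is
#' undefined and reported as `NA`.
#'
#' @param est,ref Numeric vectors of equal length (n >= 2).
#' @param joint,side Optional identifiers carried into the output.
#' @return One-row tibble: `rmse`, `cc`, `n`, `joint`, `side`.
#' @export
#' @examples
#' agreement(c(1, 2, 3), c(1.5, 2.5, 3.5))
agreement <- function(est, ref, joint = NA_character_, side = NA_character_) {
  stopifnot(length(est) == length(ref), length(est) >= 2)
  cc <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_ else {
    stats::cor(est, ref)
  }
  tibble(rmse = sqrt(mean((est - ref)^2)), cc = cc, n = length(est),
         joint = joint, side = side)
}

CHARACTERISTIC_POINTS <- c(
  "ankle_max_plantarflexion_stance", "ankle_max_dorsiflexion_stance",
  "ankle_max_plantarflexion_swing", "ankle_max_dorsiflexion_swing",
  "knee_max_extension_heel_strike", "knee_double_knee_action",
  "knee_max_extension_mid_stance", "knee_max_flexion_swing",
  "hip_max_flexion", "hip_max_extension"
)

window_extremum <- function(t, v, lo, hi, what) {
  idx <- which(t >= lo & t <= hi & !is.na(v))
  if (length(idx) < 1) return(list(value = NA_real_, index = NA_integer_))
  i <- idx[if (what == "max") which.max(v[idx]) else which.min(v[idx])]
  list(value = v[i], index = i)
}

first_local_max <- function(t, v, lo, hi) {
  idx <- which(t >= lo & t <= hi & !is.na(v))
  if (length(idx) < 3) return(list(value = NA_real_, index = NA_integer_))
  vv <- v[idx]
  locmax <- which(diff(sign(diff(vv))) == -2) + 1L
  if (!length(locmax)) return(list(value = NA_real_, index = NA_integer_))
  i <- idx[locmax[1]]
  list(value = v[i], index = i)
}

#' Extract the ten characteristic joint-angle points per stride
#'
#' For each retained stride, locates ten clinically interpretable extrema of
#' the hip, knee, and ankle angle curves. Phase windows are fixed fractions
#' of the detected stride: the swing window is the detected movement
#' interval; stance runs from the movement end to the next movement onset;
#' "around heel strike" is +/-10% of the stride duration around the stance
#' onset; "double knee action" is the first knee-flexion local maximum in
#' the first 40% of stance; "around mid stance" is the middle third of
#' stance. A missing extremum is reported as `NA`, never fabricated.
#' Strides flagged `end_not_detected`, and the final stride (whose stance
#' window is incomplete), are excluded.
#'
#' @param angles Tibble with columns `t`, `hip`, `knee`, `ankle` (deg) for
#'   one side, on a common grid.
#' @param strides A [analyze_gait()] stride table for the same side.
#' @return Tibble: `stride_index`, `point`, `value_deg`, `t`, `index`.
#' @export
extract_points <- function(angles, strides) {
  stopifnot(all(c("t", "hip", "knee", "ankle") %in% names(angles)))
  ok <- !strides$end_not_detected
  rows <- list()
  for (i in which(ok)) {
    nxt <- strides$stride_index[i] + 1L
    j <- match(nxt, strides$stride_index)
    swing_lo <- strides$t_start[i]
    swing_hi <- strides$t_end[i]
    stance_lo <- strides$t_end[i]
    ## stance runs to the next movement onset; for the final stride, to the
    ## end of the recording (a trial normally ends standing)
    stance_hi <- if (!is.na(j)) strides$t_start[j] else max(angles$t)
    if (stance_hi - stance_lo < 0.05) next  # no usable stance window
    dur <- stance_hi - swing_lo
    stance_len <- stance_hi - stance_lo
    hs <- stance_lo  # heel strike ~ stance onset (movement offset)
    win <- list(
      ankle_max_plantarflexion_stance = c(stance_lo, stance_hi, "min", "ankle"),
      ankle_max_dorsiflexion_stance = c(stance_lo, stance_hi, "max", "ankle"),
      ankle_max_plantarflexion_swing = c(swing_lo, swing_hi, "min", "ankle"),
      ankle_max_dorsiflexion_swing = c(swing_lo, swing_hi, "max", "ankle"),
      knee_max_extension_heel_strike = c(hs - 0.1 * dur, hs + 0.1 * dur,
                                         "min", "knee"),
      knee_max_extension_mid_stance = c(stance_lo + stance_len / 3,
                                        stance_hi - stance_len / 3,
                                        "min", "knee"),
      knee_max_flexion_swing = c(swing_lo, swing_hi, "max", "knee"),
      hip_max_flexion = c(swing_lo, stance_hi, "max", "hip"),
      hip_max_extension = c(swing_lo, stance_hi, "min", "hip")
    )
    for (nm in names(win)) {
      w <- win[[nm]]
      r <- window_extremum(angles$t, angles[[w[4]]],
                           as.numeric(w[1]), as.numeric(w[2]), w[3])
      rows[[length(rows) + 1L]] <- tibble(
        stride_index = strides$stride_index[i], point = nm,
        value_deg = r$value,
        t = if (is.na(r$index)) NA_real_ else angles$t[r$index],
        index = r$index)
    }
    r <- first_local_max(angles$t, angles$knee, stance_lo,
                         stance_lo + 0.4 * stance_len)
    rows[[length(rows) + 1L]] <- tibble(
      stride_index = strides$stride_index[i],
      point = "knee_double_knee_action", value_deg = r$value,
      t = if (is.na(r$index)) NA_real_ else angles$t[r$index],
      index = r$index)
  }
  if (!length(rows)) {
    return(tibble(stride_index = integer(), point = character(),
                  value_deg = numeric(), t = numeric(), index = integer()))
  }
  out <- dplyr::bind_rows(rows)
  out$point <- factor(out$point, levels = CHARACTERISTIC_POINTS)
  dplyr::arrange(out, .data$stride_index, .data$point)
}

#' Correlate characteristic points with stride velocity and length
#'
#' Pearson correlation, per characteristic point, between the point's
#' joint-angle value across strides and the estimated stride velocity and
#' stride length of the same strides.
#'
#' @param points Output of [extract_points()].
#' @param strides Stride table with `stride_index`, `velocity_mps`,
#'   `length_m`.
#' @return Tibble: `point`, `r_velocity`, `r_length`, `n`.
#' @export
correlate_points <- function(points, strides) {
  joined <- dplyr::inner_join(points,
                              strides[, c("stride_index", "velocity_mps",
                                          "length_m")],
                              by = "stride_index")
  joined <- dplyr::filter(joined, !is.na(.data$value_deg))
  if (length(unique(joined$stride_index)) < 3) {
    abort("at least 3 strides are required")
  }
  dplyr::summarise(
    dplyr::group_by(joined, .data$point),
    r_velocity = stats::cor(.data$value_deg, .data$velocity_mps),
    r_length = stats::cor(.data$value_deg, .data$length_m),
    n = dplyr::n(), .groups = "drop")
}
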