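#' Per-step movement metrics of a track
#'
#' One row per consecutive fix pair: step length (m), duration (s), speed
#' (m/s), compass heading of the step, and the signed turning angle between
#' consecutive headings. Turning angles are counterclockwise-positive
#' (a right/clockwise turn is negative) and wrapped to `(-180, 180]`; the
#' first step has no turning angle. Irregular sampling is carried through as
#' longer durations; no resampling or interpolation is performed.
#'
#' @param track a [Track-class] with at least 2 fixes.
#' @return data.frame with `length(track) - 1` rows and columns
#'   `step_length_m`, `duration_s`, `speed_m_per_s`, `heading_deg`
#'   (in `[0, 360)`), `turning_angle_deg`.
#' @examples
#' tr <- Track("e1", "a1", cbind(c(0, 0, 1000), c(0, 1000, 1000)),
#'             as.POSIXct("2020-03-01", tz = "UTC") + c(0, 1800, 3600))
#' stepSeries(tr)  # two 1000 m steps at 0.556 m/s; right turn = -90
#' @export
stepSeries <- function(track) {
  stopifnot(is(track, "Track"))
  xy <- coords(track)
  n <- nrow(xy)
  a <- xy[-n, , drop = FALSE]
  b <- xy[-1, , drop = FALSE]
  len <- geodesicDistance(a, b, coordFrame(track))
  dur <- diff(as.numeric(fixTimes(track)))
  # zero-length steps (stationary animal) have no heading; keep NA and let
  # downstream circular summaries drop them
  hdg <- suppressWarnings(compassBearing(a, b, coordFrame(track)))
  turn <- c(NA_real_, circDiff(hdg[-length(hdg)], hdg[-1]))
  data.frame(step_length_m = len, duration_s = dur, speed_m_per_s = len / dur,
             heading_deg = hdg, turning_angle_deg = turn)
}
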