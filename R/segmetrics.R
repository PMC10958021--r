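# Per-segment movement summaries and the homing-duration vs segment-count
# correlation.

#' Per-segment movement metrics
#'
#' For each segment of a segmentation: average speed (segment path length /
#' segment duration), straightness as the mean resultant length r of the
#' segment's step headings (one unit vector per step, unweighted), and the
#' proportion of the whole track, defined by step count (invariant to gap
#' handling; `proportionBy = "duration"` switches to time share). Segments
#' are numbered 1..K in time order. With `alignBy = "profile"`, two-segment
#' tracks additionally get an `aligned_label` in S1/S2/S3: the segment with
#' the higher speed-straightness profile is pinned to S2 (the homing
#' phase), so a two-segment track whose fast segment comes first reads
#' S2, S3 (missing exploratory phase); other tracks keep their time-order
#' labels.
#'
#' @param track a [Track-class].
#' @param segmentation a [SegmentationResult-class] for that track's step
#'   series.
#' @param proportionBy `"steps"` (default) or `"duration"`.
#' @param alignBy `"order"` (default) or `"profile"`.
#' @return data.frame, one row per segment: `event_id`, `segment_index`,
#'   `n_steps`, `duration_s`, `path_length_m`, `avg_speed_m_per_s`,
#'   `straightness_r`, `proportion`, and `aligned_label` when profile
#'   alignment is on.
#' @export
summarizeSegments <- function(track, segmentation,
                              proportionBy = c("steps", "duration"),
                              alignBy = c("order", "profile")) {
  proportionBy <- match.arg(proportionBy)
  alignBy <- match.arg(alignBy)
  stopifnot(is(track, "Track"), is(segmentation, "SegmentationResult"))
  ss <- stepSeries(track)
  b <- segmentBounds(segmentation)
  if (b[nrow(b), 2] != nrow(ss) + 1L)
    stop("segmentation does not match the track's step series", call. = FALSE)
  rows <- lapply(seq_len(nrow(b)), function(k) {
    idx <- b[k, 1]:(b[k, 2] - 1L)
    seg <- ss[idx, , drop = FALSE]
    hd <- seg$heading_deg[!is.na(seg$heading_deg)]
    r <- if (length(hd)) meanVector(hd)$r else NA_real_
    data.frame(event_id = eventId(track), segment_index = k,
               n_steps = length(idx), duration_s = sum(seg$duration_s),
               path_length_m = sum(seg$step_length_m),
               avg_speed_m_per_s = sum(seg$step_length_m) / sum(seg$duration_s),
               straightness_r = r, proportion = NA_real_)
  })
  out <- do.call(rbind, rows)
  out$proportion <- if (proportionBy == "steps") {
    out$n_steps / sum(out$n_steps)
  } else {
    out$duration_s / sum(out$duration_s)
  }
  if (alignBy == "profile") {
    K <- nrow(out)
    labels <- paste0("S", seq_len(K))
    if (K == 2) {
      # the faster, straighter segment is the homing phase (S2)
      profile <- rank(out$avg_speed_m_per_s) + rank(out$straightness_r)
      fast <- which.max(profile)
      labels <- paste0("S", seq_len(K) - fast + 2L)
    }
    out$aligned_label <- labels
  }
  out
}

#' Homing duration vs number of segments (Pearson)
#'
#' Correlates the number of days a homed animal needed to return with the
#' number of trajectory segments its track was split into, via the standard
#' Pearson product-moment test (two-sided t reference,
#' `t = r sqrt((n-2)/(1-r^2))`, df = n - 2).
#'
#' @param days numeric homing times in days (homed events only).
#' @param k integer chosen segment counts, parallel to `days`.
#' @return list with `n`, `pearson_r`, `t_statistic`, `df`, `p_value`;
#'   `status = "degenerate"` with NA results when either variable has zero
#'   variance.
#' @export
daysVsSegments <- function(days, k) {
  stopifnot(length(days) == length(k))
  n <- length(days)
  if (n < 3) stop("need at least 3 homed events", call. = FALSE)
  if (stats::sd(days) == 0 || stats::sd(k) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(n = n, pearson_r = NA_real_, t_statistic = NA_real_,
                df = n - 2L, p_value = NA_real_, status = "degenerate"))
  }
  ct <- stats::cor.test(days, as.numeric(k), method = "pearson")
  list(n = n, pearson_r = unname(ct$estimate), t_statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value, status = "ok")
}
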