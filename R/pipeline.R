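# Orchestration: load -> homing classification -> ring bearings -> circular
# stats per subset -> segmentation -> segment metrics -> correlation, with
# reproducible outputs and a machine-readable summary.

#' Pipeline configuration
#'
#' Defaults follow the standard analysis: rings at 100/500/1000/5000 m from
#' the release site, homing judged on a 1 km radius around home within 180
#' days, mean-contrast segmentation with lmin 4 and kmax 4, directedness
#' tested only on distributions with at least 5 bearings.
#'
#' @param frame `"geographic"` or `"planar"`.
#' @param rings ring radii (m), strictly increasing.
#' @param homingRadiusM,windowDays homing criterion.
#' @param segmentation a [segmentationConfig()].
#' @param minN minimum bearings per tested distribution.
#' @param B,alpha bootstrap resamples and significance level.
#' @param seed integer master seed; stage streams are derived from it.
#' @param ringRule see [ringBearing()].
#' @param useRandomIntercept use the mixed directedness test.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(frame = c("geographic", "planar"),
                           rings = c(100, 500, 1000, 5000),
                           homingRadiusM = 1000, windowDays = 180,
                           segmentation = segmentationConfig(),
                           minN = 5, B = 10000, alpha = 0.05, seed = 1L,
                           ringRule = c("first_beyond", "nearest"),
                           useRandomIntercept = TRUE) {
  frame <- match.arg(frame)
  ringRule <- match.arg(ringRule)
  stopifnot(all(diff(rings) > 0))
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Headline homing summary
#'
#' @param outcomes data.frame from [homingOutcomes()].
#' @return list: `n_events`, `n_homed`, `percent_homed`, `median_days`,
#'   `min_days`, `max_days` (medians/ranges over homed events only).
#' @export
summarizeHoming <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  d <- outcomes$homing_time_days[outcomes$homed]
  list(n_events = nrow(outcomes), n_homed = sum(outcomes$homed),
       percent_homed = 100 * mean(outcomes$homed),
       median_days = if (length(d)) stats::median(d) else NA_real_,
       min_days = if (length(d)) min(d) else NA_real_,
       max_days = if (length(d)) max(d) else NA_real_)
}

#' Run the full homing analysis
#'
#' @param tracks,events either loaded objects (see [readTracks()]) or `NULL`
#'   to load from `telemetryPath`/`eventPath`.
#' @param telemetryPath,eventPath input CSVs (used when `tracks` is `NULL`).
#' @param config a [pipelineConfig()].
#' @param outDir output directory; `NULL` to skip writing files.
#' @return (invisibly when writing) list with `outcomes`, `ringStats`,
#'   `segmentations` (named list of [SegmentationResult-class]),
#'   `segmentMetrics`, `correlation`, `summary`. When `outDir` is set,
#'   writes homing_outcomes.csv, ring_stats.csv, segmentation.csv,
#'   contrast_curves.csv, segment_metrics.csv, correlation.txt,
#'   summary.json and run.log.
#' @export
runPipeline <- function(tracks = NULL, events = NULL,
                        telemetryPath = NULL, eventPath = NULL,
                        config = pipelineConfig(), outDir = NULL) {
  logLines <- character(0)
  note <- function(...) logLines <<- c(logLines, sprintf(...))
  if (is.null(tracks)) {
    withCallingHandlers(
      { loaded <- readTracks(telemetryPath, eventPath, config$frame) },
      warning = function(w) { note("load: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    tracks <- loaded$tracks; events <- loaded$events
  }
  note("events analyzed: %d", nrow(events))

  outcomes <- withCallingHandlers(
    homingOutcomes(tracks, events, config$rings, config$homingRadiusM,
                   config$windowDays, config$ringRule),
    warning = function(w) { note("homing: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  rs <- ringStats(outcomes, config$minN, config$useRandomIntercept,
                  config$B, config$alpha,
                  seed = deriveSeed(config$seed, "bootstrap"))

  segcfg <- config$segmentation
  segs <- list()
  segRows <- list(); curveRows <- list(); metricRows <- list()
  for (eid in outcomes$event_id[outcomes$homed]) {
    tr <- tracks[[eid]]
    if (nFixes(tr) - 1 < segcfg$lmin) {
      note("segmentation: event %s skipped (fewer than lmin steps)", eid)
      next
    }
    sg <- withCallingHandlers(segmentTrack(tr, segcfg),
      warning = function(w) { note("segmentation %s: %s", eid, conditionMessage(w))
                              invokeRestart("muffleWarning") })
    segs[[eid]] <- sg
    b <- segmentBounds(sg)
    tm <- fixTimes(tr)
    segRows[[eid]] <- data.frame(
      event_id = eid, chosen_K = chosenK(sg), segment_index = seq_len(nrow(b)),
      start_fix_index = b[, 1], end_fix_index = b[, 2],
      start_time = format(tm[b[, 1]], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      end_time = format(tm[b[, 2]], "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    cc <- contrastCurve(sg)
    curveRows[[eid]] <- data.frame(event_id = eid, cc)
    metricRows[[eid]] <- summarizeSegments(tr, sg)
  }
  segTable <- do.call(rbind, segRows)
  curveTable <- do.call(rbind, curveRows)
  metricTable <- do.call(rbind, metricRows)

  homedDays <- outcomes$homing_time_days[match(names(segs), outcomes$event_id)]
  ks <- vapply(segs, chosenK, integer(1))
  corr <- if (length(segs) >= 3 && stats::sd(homedDays) > 0 && stats::sd(ks) > 0)
    daysVsSegments(homedDays, ks)
  else list(n = length(segs), pearson_r = NA_real_, t_statistic = NA_real_,
            df = NA_integer_, p_value = NA_real_, status = "insufficient_data")

  hs <- summarizeHoming(outcomes)
  kHist <- table(factor(ks, levels = 1:segcfg$kmax))
  pcols <- rs[rs$subset == "homed", c("ring", "p")]
  summary <- list(
    n_events = hs$n_events, n_homed = hs$n_homed,
    percent_homed = hs$percent_homed, median_homing_days = hs$median_days,
    min_homing_days = hs$min_days, max_homing_days = hs$max_days,
    ring_p_homed = stats::setNames(as.list(pcols$p), paste0("ring_", pcols$ring)),
    chosen_K_histogram = stats::setNames(as.list(as.integer(kHist)),
                                         paste0("K", names(kHist))),
    pearson_r_days_vs_segments = corr$pearson_r,
    pearson_p_days_vs_segments = corr$p_value,
    seed = config$seed)

  result <- list(outcomes = outcomes, ringStats = rs, segmentations = segs,
                 segmentTable = segTable, contrastCurves = curveTable,
                 segmentMetrics = metricTable, correlation = corr,
                 summary = summary, log = logLines)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) if (!is.null(df))
      utils::write.csv(df, file.path(outDir, f), row.names = FALSE, quote = FALSE)
    w(outcomes, "homing_outcomes.csv")
    w(rs, "ring_stats.csv")
    w(segTable, "segmentation.csv")
    w(curveTable, "contrast_curves.csv")
    w(metricTable, "segment_metrics.csv")
    writeLines(sprintf("r=%s t=%s df=%s p=%s",
                       format(corr$pearson_r), format(corr$t_statistic),
                       format(corr$df), format(corr$p_value)),
               file.path(outDir, "correlation.txt"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(sprintf("HomingTrack %s",
                         as.character(utils::packageVersion("HomingTrack"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("frame: %s; rings: %s; homing: %gm/%gd",
                         config$frame, paste(config$rings, collapse = ","),
                         config$homingRadiusM, config$windowDays),
                 logLines),
               file.path(outDir, "run.log"))
    return(invisible(result))
  }
  result
}
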