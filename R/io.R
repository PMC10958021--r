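# Telemetry / event-table I/O. Both tables are header CSVs; extra columns are
# ignored. The geographic dialect uses lon/lat (and home_lon, ..., release_lat),
# the planar dialect x/y (home_x, ..., release_y) in meters.

telemetryCols <- function(frame) {
  c("event_id", "animal_id", "timestamp",
    if (frame == "geographic") c("lon", "lat") else c("x", "y"))
}

eventCols <- function(frame) {
  pos <- if (frame == "geographic") c("lon", "lat") else c("x", "y")
  c("event_id", "animal_id", paste0("home_", pos), paste0("release_", pos),
    "release_time")
}

requireCols <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

parseTimes <- function(x, tz, what) {
  x <- as.character(x)
  t <- as.POSIXct(rep(NA_character_, length(x)), tz = tz)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(t)
    if (!any(miss)) break
    t[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = tz))
  }
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: unparseable timestamp '%s' at data row %d", what,
                 x[bad[1]], bad[1]), call. = FALSE)
  attr(t, "tzone") <- "UTC"
  t
}

#' Read an event table
#'
#' @param path CSV with columns `event_id`, `animal_id`, home and release
#'   positions (`home_lon`/`home_lat`/`release_lon`/`release_lat`, or the
#'   `_x`/`_y` forms for the planar frame), `release_time` (ISO-8601).
#' @param frame `"geographic"` or `"planar"`.
#' @param tz input timezone of timestamps (normalized to UTC on load).
#' @return data.frame of translocation events with a derived
#'   `translocation_distance_m` column (home-to-release distance).
#' @export
readEventTable <- function(path, frame = c("geographic", "planar"), tz = "UTC") {
  frame <- match.arg(frame)
  if (!file.exists(path)) stop("event table not found: ", path, call. = FALSE)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  requireCols(ev, eventCols(frame), "event table")
  pos <- if (frame == "geographic") c("lon", "lat") else c("x", "y")
  ev$release_time <- parseTimes(ev$release_time, tz, "event table")
  ev$event_id <- as.character(ev$event_id)
  ev$animal_id <- as.character(ev$animal_id)
  if (anyDuplicated(ev$event_id))
    stop("event table has duplicated event_id", call. = FALSE)
  home <- as.matrix(ev[, paste0("home_", pos)])
  release <- as.matrix(ev[, paste0("release_", pos)])
  ev$translocation_distance_m <- geodesicDistance(home, release, frame)
  if (any(ev$translocation_distance_m <= 0))
    stop("event table: home and release positions must differ", call. = FALSE)
  ev
}

#' Read telemetry and link it to translocation events
#'
#' Loads the fix table, links each fix to its event, drops fixes taken before
#' the event's release time (the homing analysis starts at release; one
#' warning reports the count), sorts fixes by time, and excludes events left
#' with fewer than 2 post-release fixes (reported by warning).
#'
#' @param telemetryPath CSV with columns `event_id`, `animal_id`, `timestamp`
#'   (ISO-8601), and `lon`/`lat` or `x`/`y`.
#' @param eventPath event-table CSV, see [readEventTable()].
#' @inheritParams readEventTable
#' @return list with `tracks` (list of [Track-class], named by event id) and
#'   `events` (data.frame, only events that yielded a track).
#' @export
readTracks <- function(telemetryPath, eventPath,
                       frame = c("geographic", "planar"), tz = "UTC") {
  frame <- match.arg(frame)
  events <- readEventTable(eventPath, frame, tz)
  if (!file.exists(telemetryPath))
    stop("telemetry file not found: ", telemetryPath, call. = FALSE)
  fx <- utils::read.csv(telemetryPath, stringsAsFactors = FALSE)
  requireCols(fx, telemetryCols(frame), "telemetry")
  pos <- if (frame == "geographic") c("lon", "lat") else c("x", "y")
  fx$event_id <- as.character(fx$event_id)
  fx$timestamp <- parseTimes(fx$timestamp, tz, "telemetry")

  unknown <- setdiff(unique(fx$event_id), events$event_id)
  if (length(unknown))
    stop("telemetry references event_id absent from event table: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  pre <- fx$timestamp < events$release_time[match(fx$event_id, events$event_id)]
  notifyDrop("pre-release fix(es)", sum(pre))
  fx <- fx[!pre, , drop = FALSE]

  tracks <- list()
  for (i in seq_len(nrow(events))) {
    eid <- events$event_id[i]
    sub <- fx[fx$event_id == eid, , drop = FALSE]
    sub <- sub[order(sub$timestamp), , drop = FALSE]
    if (anyDuplicated(sub$timestamp))
      stop(sprintf("event '%s': duplicate timestamps in telemetry", eid),
           call. = FALSE)
    if (nrow(sub) < 2L) next
    tracks[[eid]] <- Track(eid, events$animal_id[i],
                           coords = as.matrix(sub[, pos]),
                           time = sub$timestamp, frame = frame)
  }
  dropped <- setdiff(events$event_id, names(tracks))
  notifyDrop("event(s) with < 2 post-release fixes", length(dropped))
  events <- events[events$event_id %in% names(tracks), , drop = FALSE]
  tracks <- tracks[events$event_id]
  list(tracks = tracks, events = events)
}

#' Write tracks and events back to the CSV dialects
#'
#' @param tracks list of [Track-class] objects.
#' @param events event data.frame as returned by [readEventTable()].
#' @param telemetryPath,eventPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeTracks <- function(tracks, events, telemetryPath, eventPath) {
  rows <- lapply(tracks, function(tr) {
    data.frame(event_id = eventId(tr), animal_id = animalId(tr),
               timestamp = format(fixTimes(tr), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               coords(tr), check.names = FALSE)
  })
  tel <- do.call(rbind, rows)
  rownames(tel) <- NULL
  utils::write.csv(tel, telemetryPath, row.names = FALSE, quote = FALSE)
  ev <- events
  ev$release_time <- format(ev$release_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(ev, eventPath, row.names = FALSE, quote = FALSE)
  invisible(c(telemetryPath, eventPath))
}

# Home/release positions of one event row as length-2 numerics.
eventHome <- function(event, frame) {
  pos <- if (frame == "geographic") c("lon", "lat") else c("x", "y")
  as.numeric(event[1, paste0("home_", pos)])
}

eventRelease <- function(event, frame) {
  pos <- if (frame == "geographic") c("lon", "lat") else c("x", "y")
  as.numeric(event[1, paste0("release_", pos)])
}
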