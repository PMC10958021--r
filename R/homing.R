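# Homing-success classification and ring bearings. Two distinct circles are
# involved: homing is judged on distance from the HOME (capture) site, ring
# bearings on distance from the RELEASE site.

#' Classify homing success of one translocation event
#'
#' An event is homed when some fix within `windowDays` of release lies at or
#' inside `radiusM` of the home (capture) location — "reached or crossed", so
#' a fix exactly on the boundary counts. Homing time is measured to the first
#' such fix. Appending fixes after the first qualifying fix cannot change the
#' outcome.
#'
#' @param track post-release [Track-class].
#' @param event one-row data.frame from [readEventTable()].
#' @param radiusM homing radius around the home site, meters.
#' @param windowDays analysis window after release, days.
#' @return list with `event_id`, `animal_id`, `homed` (logical),
#'   `homing_time_days` (`NA` when not homed), `first_home_fix` (row index
#'   into the track's fixes, `NA` when not homed).
#' @export
classifyHoming <- function(track, event, radiusM = 1000, windowDays = 180) {
  stopifnot(is(track, "Track"), nrow(event) == 1L)
  frame <- coordFrame(track)
  home <- eventHome(event, frame)
  relTime <- as.numeric(event$release_time[1])
  tdays <- (as.numeric(fixTimes(track)) - relTime) / 86400
  d <- geodesicDistance(coords(track), matrix(home, nrow = 1), frame)
  ok <- which(d <= radiusM & tdays <= windowDays)
  if (length(ok)) {
    i <- ok[1]
    list(event_id = eventId(track), animal_id = animalId(track), homed = TRUE,
         homing_time_days = tdays[i], first_home_fix = i)
  } else {
    list(event_id = eventId(track), animal_id = animalId(track), homed = FALSE,
         homing_time_days = NA_real_, first_home_fix = NA_integer_)
  }
}

#' Bearing at a distance ring around the release site
#'
#' Scans fixes in time order and selects the first fix at or beyond
#' `radiusM` from the release location ("at least" the ring distance); the
#' bearing is the compass direction release -> that fix, and
#' `home_relative_deg` rotates it so 0 means exactly homeward. With
#' `rule = "nearest"` the fix with distance closest to the ring radius among
#' fixes at/beyond it is used instead.
#'
#' @inheritParams classifyHoming
#' @param radiusM ring radius, meters.
#' @param rule `"first_beyond"` (default) or `"nearest"`.
#' @return list with `radius_m`, `crossed`, and (when crossed) `fix_index`,
#'   `bearing_deg`, `home_relative_deg`.
#' @export
ringBearing <- function(track, event, radiusM, rule = c("first_beyond", "nearest")) {
  rule <- match.arg(rule)
  stopifnot(is(track, "Track"), nrow(event) == 1L)
  frame <- coordFrame(track)
  release <- eventRelease(event, frame)
  home <- eventHome(event, frame)
  d <- geodesicDistance(coords(track), matrix(release, nrow = 1), frame)
  beyond <- which(d >= radiusM)
  if (!length(beyond))
    return(list(radius_m = radiusM, crossed = FALSE, fix_index = NA_integer_,
                bearing_deg = NA_real_, home_relative_deg = NA_real_))
  i <- if (rule == "first_beyond") beyond[1] else beyond[which.min(d[beyond] - radiusM)]
  b <- compassBearing(release, coords(track)[i, ], frame)
  hb <- compassBearing(release, home, frame)
  list(radius_m = radiusM, crossed = TRUE, fix_index = i,
       bearing_deg = b, home_relative_deg = wrap360(b - hb))
}

#' Homing outcomes for a whole study
#'
#' Runs [classifyHoming()] and [ringBearing()] (at every ring) for each
#' event. Events released closer to home than a ring radius cannot meaningly
#' cross that ring outward toward home; such rings are reported not-crossed
#' with a warning.
#'
#' @param tracks named list of [Track-class] (as from [readTracks()]).
#' @param events event data.frame.
#' @param rings ring radii in meters, strictly increasing.
#' @param radiusM,windowDays homing criterion, see [classifyHoming()].
#' @param rule ring-fix selection rule, see [ringBearing()].
#' @return data.frame, one row per event: `event_id`, `animal_id`, `homed`,
#'   `homing_time_days`, then per ring `bearing_deg_<r>` and
#'   `home_relative_deg_<r>`.
#' @export
homingOutcomes <- function(tracks, events, rings = c(100, 500, 1000, 5000),
                           radiusM = 1000, windowDays = 180,
                           rule = c("first_beyond", "nearest")) {
  rule <- match.arg(rule)
  stopifnot(all(diff(rings) > 0))
  shortEvents <- 0L
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, , drop = FALSE]
    tr <- tracks[[ev$event_id]]
    cl <- classifyHoming(tr, ev, radiusM, windowDays)
    out <- data.frame(event_id = cl$event_id, animal_id = cl$animal_id,
                      homed = cl$homed, homing_time_days = cl$homing_time_days)
    for (r in rings) {
      if (r >= ev$translocation_distance_m) {
        rb <- list(crossed = FALSE, bearing_deg = NA_real_,
                   home_relative_deg = NA_real_)
        shortEvents <<- shortEvents + 1L
      } else {
        rb <- ringBearing(tr, ev, r, rule)
      }
      out[[paste0("bearing_deg_", r)]] <- rb$bearing_deg
      out[[paste0("home_relative_deg_", r)]] <- rb$home_relative_deg
    }
    out
  })
  if (shortEvents > 0)
    warning(sprintf(
      "%d ring(s) at or beyond the translocation distance marked not crossed",
      shortEvents), call. = FALSE)
  do.call(rbind, rows)
}

#' Long-format bearing table for circular analysis
#'
#' @param outcomes data.frame from [homingOutcomes()].
#' @param subset `"all"`, `"homed"`, or `"not_homed"`; `"all"` is the union
#'   of the other two (the homed flag partitions events).
#' @return data.frame with one row per crossed ring per selected event:
#'   `event_id`, `animal_id`, `ring`, `home_relative_deg`.
#' @export
bearingTable <- function(outcomes, subset = c("all", "homed", "not_homed")) {
  subset <- match.arg(subset)
  sel <- switch(subset, all = rep(TRUE, nrow(outcomes)),
                homed = outcomes$homed, not_homed = !outcomes$homed)
  oc <- outcomes[sel, , drop = FALSE]
  relCols <- grep("^home_relative_deg_", names(oc), value = TRUE)
  rings <- as.numeric(sub("^home_relative_deg_", "", relCols))
  rows <- lapply(seq_along(relCols), function(j) {
    v <- oc[[relCols[j]]]
    keep <- !is.na(v)
    data.frame(event_id = oc$event_id[keep], animal_id = oc$animal_id[keep],
               ring = rings[j], home_relative_deg = v[keep])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$ring), , drop = FALSE]
}
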