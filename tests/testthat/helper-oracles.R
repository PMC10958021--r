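# Independent oracles and fixture builders used across the suite.

# Haversine distance written directly from the formula (independent of the
# package's geodesy path).
oracleHaversine <- function(a, b, R = 6371008.8) {
  toRad <- pi / 180
  dlat <- (b[2] - a[2]) * toRad
  dlon <- (b[1] - a[1]) * toRad
  h <- sin(dlat / 2)^2 + cos(a[2] * toRad) * cos(b[2] * toRad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(h))
}

# Spherical initial azimuth from the standard forward-azimuth formula.
oracleAzimuth <- function(a, b) {
  toRad <- pi / 180
  l1 <- a[2] * toRad; l2 <- b[2] * toRad; dl <- (b[1] - a[1]) * toRad
  y <- sin(dl) * cos(l2)
  x <- cos(l1) * sin(l2) - sin(l1) * cos(l2) * cos(dl)
  (atan2(y, x) * 180 / pi) %% 360
}

# Naive two-pass contrast (mean type) of series[i..j-1].
oracleContrastMean <- function(y, i, j) {
  seg <- y[i:(j - 1)]
  sum((seg - mean(seg))^2)
}

# Exhaustive enumeration of all partitions of 1..n into exactly K contiguous
# segments of length >= lmin; returns the minimal total mean-contrast and
# its boundaries.
oracleBestPartition <- function(y, K, lmin) {
  n <- length(y)
  best <- Inf
  bestB <- NULL
  recurse <- function(start, k, acc) {
    if (k == 1) {
      if (n - start + 1 >= lmin) {
        bounds <- c(acc, list(c(start, n + 1)))
        tot <- sum(vapply(bounds, function(b) oracleContrastMean(y, b[1], b[2]),
                          numeric(1)))
        if (tot < best - 1e-12) {
          best <<- tot
          bestB <<- bounds
        }
      }
      return(invisible())
    }
    ends <- (start + lmin):(n - (k - 1) * lmin + 1)
    for (e in ends) recurse(e, k - 1, c(acc, list(c(start, e))))
  }
  if (n >= K * lmin) recurse(1, K, list())
  list(J = best, boundaries = if (is.null(bestB)) NULL else do.call(rbind, bestB))
}

# Minimal planar track from coordinates at a fixed 30-min cadence.
makeTrack <- function(xy, eventId = "e1", animalId = "a1",
                      t0 = as.POSIXct("2021-03-01 06:00:00", tz = "UTC"),
                      dt = 1800) {
  Track(eventId, animalId, as.matrix(xy), t0 + dt * (seq_len(nrow(xy)) - 1),
        frame = "planar")
}

# One-row planar event table for home/release geometry.
makeEvent <- function(home = c(0, 11900), release = c(0, 0),
                      eventId = "e1", animalId = "a1",
                      releaseTime = as.POSIXct("2021-03-01 06:00:00", tz = "UTC")) {
  data.frame(event_id = eventId, animal_id = animalId,
             home_x = home[1], home_y = home[2],
             release_x = release[1], release_y = release[2],
             release_time = releaseTime,
             translocation_distance_m = sqrt(sum((home - release)^2)))
}

# Uniform-turning random-walk track (no phase structure), for null cases.
makeRandomWalkTrack <- function(n = 100, stepMean = 150, seed = 1,
                                eventId = "rw") {
  set.seed(seed)
  h <- cumsum(c(runif(1, 0, 360), runif(n - 1, -120, 120)))
  len <- rgamma(n, shape = 4, scale = stepMean / 4)
  xy <- rbind(c(0, 0), cbind(cumsum(len * sin(h * pi / 180)),
                             cumsum(len * cos(h * pi / 180))))
  makeTrack(xy, eventId = eventId)
}

# The frozen synthetic study used by end-to-end tests (kept small enough to
# simulate in seconds; identical call in scripts/acceptance.R). Memoized per
# seed so repeated tests do not re-simulate.
.studyCache <- new.env(parent = emptyenv())
frozenStudy <- function(seed = 7) {
  key <- as.character(seed)
  if (is.null(.studyCache[[key]]))
    .studyCache[[key]] <- suppressWarnings(simulateStudy(studySpec(seed = seed)))
  .studyCache[[key]]
}

vonMisesDeg <- function(n, muDeg, kappa) {
  wrap360(muDeg + 180 / pi * HomingTrack:::rvonmises(n, 0, kappa))
}
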