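# Synthetic translocation studies with known ground truth: three-phase
# biased correlated random-walk (BCRW) homing tracks, repeated-translocation
# structure, and non-homing wanderers. Every stochastic element is driven by
# an explicit seed; identical seeds give byte-identical CSV output.

# von Mises sampler (Best & Fisher 1979 wrapping method); mu in radians.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return((mu + stats::runif(n, -pi, pi) + pi) %% (2 * pi) - pi)
  if (kappa > 5e4) return(mu + stats::rnorm(n) / sqrt(kappa))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- n - filled
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    if (any(ok)) {
      out[(filled + 1):(filled + sum(ok))] <- th
      filled <- filled + sum(ok)
    }
  }
  (mu + out + pi) %% (2 * pi) - pi
}

#' Movement-phase specification for the BCRW generator
#'
#' Headings evolve as a weighted circular combination of the bearing to a
#' goal (`biasWeight`) and the previous heading (`persistenceWeight`), plus
#' von Mises noise of concentration `kappa`; step lengths are gamma with
#' mean `stepMeanM` and shape `stepShape` (shape `Inf` = constant steps).
#'
#' @param name phase label.
#' @param biasWeight weight toward the goal, in `[0, 1]`.
#' @param persistenceWeight weight toward the previous heading;
#'   `biasWeight + persistenceWeight <= 1`.
#' @param kappa von Mises concentration of the heading noise (>= 0).
#' @param stepMeanM mean step length, meters per 30-min step.
#' @param stepShape gamma shape (sd = mean / sqrt(shape)); `Inf` for
#'   constant steps.
#' @param durationSteps fixed phase duration in steps (`NA` for phases
#'   ended by a distance stopping rule).
#' @param burstSteps,burstBiasWeight,burstKappa an optional initial
#'   homeward-biased burst (used by the default exploratory phase to emulate
#'   orientation immediately after release followed by unoriented
#'   exploration).
#' @return a list of class `"PhaseSpec"`.
#' @export
phaseSpec <- function(name, biasWeight, persistenceWeight, kappa,
                      stepMeanM, stepShape = 4, durationSteps = NA_integer_,
                      burstSteps = 0L, burstBiasWeight = biasWeight,
                      burstKappa = kappa) {
  stopifnot(biasWeight >= 0, persistenceWeight >= 0,
            biasWeight + persistenceWeight <= 1, kappa >= 0, stepMeanM > 0)
  structure(list(name = name, biasWeight = biasWeight,
                 persistenceWeight = persistenceWeight, kappa = kappa,
                 stepMeanM = stepMeanM, stepShape = stepShape,
                 durationSteps = durationSteps, burstSteps = as.integer(burstSteps),
                 burstBiasWeight = burstBiasWeight, burstKappa = burstKappa),
            class = "PhaseSpec")
}

#' Default three-phase homing template
#'
#' Slow, tortuous exploration (with a 3-step homeward burst right after
#' release), a fast and straight homing phase that ends on first entry
#' within `arrivalRadiusM` of home, and a slow, weakly biased arrival phase
#' that ends within the homing radius. Step-length means differ strongly
#' between phases, which is what makes the phases recoverable by
#' mean-contrast segmentation.
#'
#' @param exploratorySteps duration of the exploratory phase in 30-min
#'   steps (drawn per event by [simulateStudy()]).
#' @return named list of [phaseSpec()]s.
#' @export
defaultPhases <- function(exploratorySteps = 48L) {
  list(
    exploratory = phaseSpec("exploratory", biasWeight = 0,
                            persistenceWeight = 0.3, kappa = 1,
                            stepMeanM = 150, stepShape = 4,
                            durationSteps = exploratorySteps,
                            burstSteps = 3L, burstBiasWeight = 0.8,
                            burstKappa = 4),
    homing = phaseSpec("homing", biasWeight = 0.8, persistenceWeight = 0.15,
                       kappa = 8, stepMeanM = 600, stepShape = 6),
    arrival = phaseSpec("arrival", biasWeight = 0.2, persistenceWeight = 0.3,
                        kappa = 1.5, stepMeanM = 160, stepShape = 4)
  )
}

# Wandering template for non-homing events: no attraction to home, a drift
# toward a distant pseudo-goal in a random away-from-home direction.
wanderPhase <- function(durationSteps = 480L) {
  phaseSpec("wander", biasWeight = 0.3, persistenceWeight = 0.3, kappa = 1.5,
            stepMeanM = 150, stepShape = 4, durationSteps = durationSteps)
}

drawStep <- function(spec, n = 1) {
  if (is.infinite(spec$stepShape)) rep(spec$stepMeanM, n)
  else stats::rgamma(n, shape = spec$stepShape,
                     scale = spec$stepMeanM / spec$stepShape)
}

# One BCRW step heading (compass degrees).
nextHeading <- function(goalBearing, prevHeading, w, p, kappa) {
  ux <- w * sin(deg2rad(goalBearing)) + p * sin(deg2rad(prevHeading))
  uy <- w * cos(deg2rad(goalBearing)) + p * cos(deg2rad(prevHeading))
  base <- if (ux^2 + uy^2 < 1e-24) stats::runif(1, 0, 360)
          else rad2deg(atan2(ux, uy))
  wrap360(base + rad2deg(rvonmises(1, 0, kappa)))
}

#' Simulate one translocation track
#'
#' Runs the phase list in order from the release position. Phases with
#' `durationSteps` run for that many steps; the `homing` phase runs until
#' first entry within `arrivalRadiusM` of home; the `arrival` phase until
#' first entry within `homingRadiusM`. Simulation stops at the first fix
#' within `homingRadiusM` of home, or at `maxSteps`. Coordinates are planar
#' meters (release need not be the origin). The goal of biased phases is the
#' home position unless `goal` is given (used for non-homing drift).
#'
#' @param release,home planar positions, length-2 numeric (meters).
#' @param releaseTime POSIXct release time (UTC).
#' @param phases named list of [phaseSpec()]s, applied in order.
#' @param seed integer seed.
#' @param eventId,animalId identifiers for the resulting [Track-class].
#' @param fixIntervalS fix interval, seconds.
#' @param arrivalRadiusM,homingRadiusM phase-switch and stop radii, meters
#'   (the arrival radius is wide enough that the slow arrival phase spans
#'   several fixes rather than ending on the first step).
#' @param maxSteps hard cap on the number of steps.
#' @param goal optional drift goal overriding `home` as the bias target.
#' @return list with `track` ([Track-class]) and `truth`: `homed`,
#'   `homing_time_days`, `arrival_fix`, `phase_start_steps` (named integer
#'   vector, step index at which each simulated phase begins), `n_phases`.
#' @export
simulateTrack <- function(release, home, releaseTime, phases, seed,
                          eventId = "sim", animalId = "a1",
                          fixIntervalS = 1800, arrivalRadiusM = 3000,
                          homingRadiusM = 1000, maxSteps = 6000, goal = NULL) {
  set.seed(seed)
  target <- if (is.null(goal)) home else goal
  pos <- as.numeric(release)
  coords <- matrix(NA_real_, nrow = maxSteps + 1, ncol = 2)
  coords[1, ] <- pos
  nFix <- 1L
  prevHeading <- NA_real_
  phaseStarts <- integer(0)
  distHome <- function(p) sqrt(sum((p - home)^2))
  arrived <- distHome(pos) <= homingRadiusM

  for (iPhase in seq_along(phases)) {
    spec <- phases[[iPhase]]
    lastPhase <- iPhase == length(phases)
    if (arrived || nFix > maxSteps) break
    phaseStarts[spec$name] <- nFix  # step index of first step in this phase
    stepInPhase <- 0L
    repeat {
      if (nFix > maxSteps) break
      stepInPhase <- stepInPhase + 1L
      # stopping rules; the hand-over to a following phase only applies when
      # one exists (a final homing phase runs all the way home)
      if (!is.na(spec$durationSteps) && stepInPhase > spec$durationSteps) break
      if (spec$name == "homing" && !lastPhase &&
          distHome(pos) <= arrivalRadiusM) break
      if (spec$name == "arrival" && arrived) break
      inBurst <- stepInPhase <= spec$burstSteps
      w <- if (inBurst) spec$burstBiasWeight else spec$biasWeight
      kap <- if (inBurst) spec$burstKappa else spec$kappa
      gb <- if (all(pos == target)) stats::runif(1, 0, 360)
            else compassBearing(pos, target, "planar")
      h <- nextHeading(gb, if (is.na(prevHeading)) gb else prevHeading,
                       w, if (is.na(prevHeading)) 0 else spec$persistenceWeight,
                       kap)
      len <- drawStep(spec)
      pos <- pos + len * c(sin(deg2rad(h)), cos(deg2rad(h)))
      prevHeading <- h
      nFix <- nFix + 1L
      coords[nFix, ] <- pos
      if (distHome(pos) <= homingRadiusM) { arrived <- TRUE; break }
    }
  }

  coords <- coords[seq_len(nFix), , drop = FALSE]
  time <- releaseTime + fixIntervalS * (seq_len(nFix) - 1)
  track <- Track(eventId, animalId, coords, time, frame = "planar")
  homingTime <- if (arrived) (nFix - 1) * fixIntervalS / 86400 else NA_real_
  list(track = track,
       truth = list(homed = arrived, homing_time_days = homingTime,
                    arrival_fix = if (arrived) nFix else NA_integer_,
                    phase_start_steps = phaseStarts,
                    n_phases = length(phaseStarts)))
}

#' Study-level specification for the synthetic generator
#'
#' Defaults emulate the design of a red-deer translocation experiment:
#' 35 events over 21 animals (some translocated two or three times),
#' release 11.9 +/- 1.8 km from home (truncated above 6 km), 30-min fixes,
#' and 4 of 35 events that do not home.
#'
#' @param nAnimals number of distinct animals.
#' @param nEvents number of translocation events (extra events beyond
#'   `nAnimals` are repeat translocations, at most `maxPerAnimal` each).
#' @param maxPerAnimal maximum translocations per animal.
#' @param distMeanM,distSdM,distMinM translocation-distance distribution
#'   (normal, truncated below `distMinM`), meters.
#' @param fixIntervalS fix interval, seconds.
#' @param fractionNonHoming fraction of events simulated as non-homing
#'   wanderers (rounded to a count).
#' @param fractionNoExploratory fraction of homing events that skip the
#'   exploratory phase (fast two-phase homers, emulating the structural
#'   heterogeneity real studies report).
#' @param exploratoryMeanSteps median exploratory-phase duration in steps;
#'   per-event durations are log-normal around it (sdlog
#'   `exploratorySdLog`), floored at 6 steps.
#' @param exploratorySdLog log-scale sd of the exploratory duration.
#' @param arrivalRadiusM,homingRadiusM,maxSteps see [simulateTrack()].
#' @param frame `"planar"` (release at origin, home due north) or
#'   `"geographic"` (the same geometry mapped onto the sphere around
#'   `originLonLat`, events offset eastward to keep them apart).
#' @param originLonLat length-2 lon/lat of the first release site
#'   (geographic frame only).
#' @param seed integer seed (mandatory).
#' @return list of class `"StudySpec"`.
#' @export
studySpec <- function(nAnimals = 21L, nEvents = 35L, maxPerAnimal = 3L,
                      distMeanM = 11900, distSdM = 1800, distMinM = 6000,
                      fixIntervalS = 1800, fractionNonHoming = 4 / 35,
                      fractionNoExploratory = 0.2,
                      exploratoryMeanSteps = 96, exploratorySdLog = 0.9,
                      arrivalRadiusM = 3000, homingRadiusM = 1000,
                      maxSteps = 6000, frame = c("planar", "geographic"),
                      originLonLat = c(12.7, 50.1), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  frame <- match.arg(frame)
  stopifnot(nEvents >= nAnimals, nEvents <= nAnimals * maxPerAnimal)
  structure(as.list(environment()), class = "StudySpec")
}

metersToLonLat <- function(xy, origin) {
  lat <- origin[2] + rad2deg(xy[, 2] / EARTH_RADIUS_M)
  lon <- origin[1] + rad2deg(xy[, 1] / (EARTH_RADIUS_M * cos(deg2rad(origin[2]))))
  cbind(lon = lon, lat = lat)
}

#' Simulate a whole translocation study
#'
#' Draws the event table (animals, repeat translocations, distances, release
#' times), simulates every track, and assembles ground truth. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [studySpec()].
#' @return list with `tracks` (named list of [Track-class]), `events`
#'   (data.frame in the event-table dialect), and `truth` (data.frame:
#'   `event_id`, `animal_id`, `homed`, `homing_time_days`, `arrival_fix`,
#'   `n_fixes`, `n_phases`, `homing_start_step`, `arrival_start_step`,
#'   plus `crossed_<r>` flags for the default rings).
#' @export
simulateStudy <- function(spec) {
  stopifnot(inherits(spec, "StudySpec"))
  set.seed(deriveSeed(spec$seed, "study_design"))
  nE <- spec$nEvents; nA <- spec$nAnimals
  # animal assignment: everyone once, repeats drawn among animals still
  # below maxPerAnimal
  animals <- paste0("A", formatC(seq_len(nA), width = 2, flag = "0"))
  assign <- animals
  while (length(assign) < nE) {
    open <- animals[tabulate(match(assign, animals), nA) < spec$maxPerAnimal]
    assign <- c(assign, sample(open, 1))
  }
  assign <- assign[order(match(assign, animals))]
  dist <- numeric(nE)
  for (i in seq_len(nE)) {
    repeat {
      dist[i] <- stats::rnorm(1, spec$distMeanM, spec$distSdM)
      if (dist[i] > spec$distMinM) break
    }
  }
  nNon <- round(spec$fractionNonHoming * nE)
  nonHoming <- sample(seq_len(nE), nNon)
  homingIdx <- setdiff(seq_len(nE), nonHoming)
  noExplore <- sample(homingIdx,
                      round(spec$fractionNoExploratory * length(homingIdx)))
  expSteps <- pmax(6, round(stats::rlnorm(nE, log(spec$exploratoryMeanSteps),
                                          spec$exploratorySdLog)))
  releaseTimes <- as.POSIXct("2021-02-15 06:00:00", tz = "UTC") +
    86400 * 3 * (seq_len(nE) - 1)

  eventIds <- paste0("E", formatC(seq_len(nE), width = 2, flag = "0"))
  tracks <- list()
  truthRows <- list()
  evRows <- list()
  rings <- c(100, 500, 1000, 5000)
  for (i in seq_len(nE)) {
    release <- c(0, 0)
    home <- c(0, dist[i])
    if (i %in% nonHoming) {
      # drift goal: 50 km along a random bearing pointing away from home
      set.seed(deriveSeed(spec$seed, paste0("drift", i)))
      away <- wrap360(180 + stats::runif(1, -60, 60))  # home is due north
      goal <- release + 50000 * c(sin(deg2rad(away)), cos(deg2rad(away)))
      phases <- list(wander = wanderPhase(durationSteps = 480L))
    } else {
      goal <- NULL
      phases <- defaultPhases(exploratorySteps = expSteps[i])
      if (i %in% noExplore) phases <- phases[c("homing", "arrival")]
    }
    sim <- simulateTrack(release, home, releaseTimes[i], phases,
                         seed = deriveSeed(spec$seed, paste0("track", i)),
                         eventId = eventIds[i], animalId = assign[i],
                         fixIntervalS = spec$fixIntervalS,
                         arrivalRadiusM = spec$arrivalRadiusM,
                         homingRadiusM = spec$homingRadiusM,
                         maxSteps = spec$maxSteps, goal = goal)
    tr <- sim$track
    if (spec$frame == "geographic") {
      origin <- c(spec$originLonLat[1] + 0.3 * (i - 1), spec$originLonLat[2])
      tr <- Track(eventId(tr), animalId(tr),
                  metersToLonLat(coords(tr), origin), fixTimes(tr),
                  frame = "geographic")
      homeOut <- drop(metersToLonLat(matrix(home, 1), origin))
      relOut <- drop(metersToLonLat(matrix(release, 1), origin))
    } else {
      homeOut <- home; relOut <- release
    }
    tracks[[eventIds[i]]] <- tr
    pos <- if (spec$frame == "geographic") c("lon", "lat") else c("x", "y")
    ev <- data.frame(event_id = eventIds[i], animal_id = assign[i])
    ev[paste0("home_", pos)] <- as.list(homeOut)
    ev[paste0("release_", pos)] <- as.list(relOut)
    ev$release_time <- releaseTimes[i]
    evRows[[i]] <- ev
    dRel <- sqrt(rowSums((sweep(coords(sim$track), 2, release))^2))
    tRow <- data.frame(
      event_id = eventIds[i], animal_id = assign[i],
      homed = sim$truth$homed, homing_time_days = sim$truth$homing_time_days,
      arrival_fix = sim$truth$arrival_fix, n_fixes = nFixes(tr),
      n_phases = sim$truth$n_phases,
      homing_start_step = unname(sim$truth$phase_start_steps["homing"]),
      arrival_start_step = unname(sim$truth$phase_start_steps["arrival"]))
    for (r in rings) tRow[[paste0("crossed_", r)]] <- any(dRel >= r)
    truthRows[[i]] <- tRow
  }
  events <- do.call(rbind, evRows)
  events$translocation_distance_m <- dist
  truth <- do.call(rbind, truthRows)
  list(tracks = tracks, events = events, truth = truth)
}

#' Write a simulated study to CSV
#'
#' Emits `telemetry.csv` and `events.csv` in the dialects read by
#' [readTracks()], plus `truth.csv` with the generator's ground truth.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("telemetry.csv", "events.csv", "truth.csv"))
  writeTracks(study$tracks, study$events, paths[1], paths[2])
  tr <- study$truth
  num <- vapply(tr, is.numeric, logical(1))
  tr[num] <- lapply(tr[num], function(x) round(x, 6))
  utils::write.csv(tr, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
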