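test_that("the homing boundary is inclusive and timed to the first entry", {
  ev <- makeEvent(home = c(0, 11000))
  # day 3 fix lands exactly 1000 m from home
  t0 <- ev$release_time
  tr <- Track("e1", "a1", rbind(c(0, 0), c(0, 5000), c(0, 10000), c(0, 10500)),
              t0 + c(0, 86400, 3 * 86400, 4 * 86400))
  cl <- classifyHoming(tr, ev)
  expect_true(cl$homed)
  expect_equal(cl$homing_time_days, 3)
  expect_equal(cl$first_home_fix, 3)
})

test_that("approaching no closer than 1200 m is not homing", {
  ev <- makeEvent(home = c(0, 11000))
  tr <- Track("e1", "a1", rbind(c(0, 0), c(0, 9800), c(0, 9700)),
              ev$release_time + c(0, 86400, 2 * 86400))
  expect_false(classifyHoming(tr, ev)$homed)
})

test_that("fixes outside the analysis window do not count", {
  ev <- makeEvent(home = c(0, 11000))
  tr <- Track("e1", "a1", rbind(c(0, 0), c(0, 11000)),
              ev$release_time + c(0, 181 * 86400))
  expect_false(classifyHoming(tr, ev, windowDays = 180)$homed)
  expect_true(classifyHoming(tr, ev, windowDays = 200)$homed)
})

test_that("classification is invariant to fixes appended after arrival", {
  st <- frozenStudy(seed = 5)
  i <- which(st$truth$homed)[1]
  ev <- st$events[i, , drop = FALSE]
  tr <- st$tracks[[ev$event_id]]
  base <- classifyHoming(tr, ev)
  xy <- rbind(coords(tr), coords(tr)[nFixes(tr), ] + c(5000, 5000))
  tm <- c(fixTimes(tr), fixTimes(tr)[nFixes(tr)] + 1800)
  ext <- classifyHoming(Track(eventId(tr), animalId(tr), xy, tm), ev)
  expect_equal(ext$homed, base$homed)
  expect_equal(ext$homing_time_days, base$homing_time_days)
})

test_that("generator ground truth agrees with the classifier", {
  st <- frozenStudy(seed = 5)
  oc <- suppressWarnings(homingOutcomes(st$tracks, st$events))
  expect_equal(oc$homed, st$truth$homed)
  expect_equal(oc$homing_time_days, st$truth$homing_time_days)
})

test_that("ring bearings use the first fix at or beyond the ring", {
  ev <- makeEvent(home = c(0, 11900))
  tr <- Track("e1", "a1", rbind(c(0, 0), c(0, 40), c(0, 90), c(0, 130)),
              ev$release_time + 1800 * (0:3))
  rb <- ringBearing(tr, ev, 100)
  expect_true(rb$crossed)
  expect_equal(rb$fix_index, 4)  # the 130 m fix
  expect_equal(rb$bearing_deg, 0)
  expect_equal(rb$home_relative_deg, 0)  # due north = homeward
})

test_that("a track that never reaches a ring reports crossed = FALSE", {
  ev <- makeEvent(home = c(0, 11900))
  th <- seq(0, 6 * pi, length.out = 40)
  spiral <- cbind(800 * th / max(th) * sin(th), 800 * th / max(th) * cos(th))
  tr <- makeTrack(spiral)
  expect_true(ringBearing(tr, ev, 500)$crossed)
  expect_false(ringBearing(tr, ev, 1000)$crossed)
  expect_false(ringBearing(tr, ev, 5000)$crossed)
})

test_that("first-crossing fix indices are monotone in ring radius", {
  st <- frozenStudy(seed = 5)
  rings <- c(100, 500, 1000, 5000)
  for (i in seq_len(nrow(st$events))) {
    ev <- st$events[i, , drop = FALSE]
    idx <- vapply(rings, function(r) {
      rb <- ringBearing(st$tracks[[ev$event_id]], ev, r)
      if (rb$crossed) rb$fix_index else NA_integer_
    }, integer(1))
    idx <- idx[!is.na(idx)]
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("pure homeward drift yields homeward ring bearings at every ring", {
  phases <- list(homing = phaseSpec("homing", biasWeight = 1,
                                    persistenceWeight = 0, kappa = 1e6,
                                    stepMeanM = 500, stepShape = Inf))
  ev <- makeEvent(home = c(0, 11900))
  sim <- simulateTrack(c(0, 0), c(0, 11900), ev$release_time, phases, seed = 1)
  for (r in c(100, 500, 1000, 5000)) {
    rb <- ringBearing(sim$track, ev, r)
    expect_true(rb$crossed)
    expect_lt(abs(wrap180(rb$home_relative_deg)), 0.2)
  }
})

test_that("bearing tables partition by the homed flag", {
  st <- frozenStudy(seed = 5)
  oc <- suppressWarnings(homingOutcomes(st$tracks, st$events))
  all_ <- bearingTable(oc, "all")
  homed <- bearingTable(oc, "homed")
  not <- bearingTable(oc, "not_homed")
  expect_equal(nrow(all_), nrow(homed) + nrow(not))
  expect_true(all(homed$event_id %in% oc$event_id[oc$homed]))
  expect_true(all(not$event_id %in% oc$event_id[!oc$homed]))
  # row counts per ring equal the generator's crossing bookkeeping
  for (r in c(100, 500, 1000, 5000)) {
    expect_equal(sum(all_$ring == r), sum(st$truth[[paste0("crossed_", r)]]))
  }
})

test_that("rings at or beyond the translocation distance are not evaluated", {
  st <- frozenStudy(seed = 5)
  ev <- st$events[1, , drop = FALSE]
  ev$translocation_distance_m <- 4000
  expect_warning(
    oc <- homingOutcomes(st$tracks[ev$event_id], ev),
    "translocation distance")
  expect_true(is.na(oc$home_relative_deg_5000))
})
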