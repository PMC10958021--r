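test_that("the deterministic limit is a straight homeward line", {
  phases <- list(homing = phaseSpec("homing", biasWeight = 1,
                                    persistenceWeight = 0, kappa = 1e6,
                                    stepMeanM = 500, stepShape = Inf))
  sim <- simulateTrack(c(0, 0), c(0, 11900),
                       as.POSIXct("2021-03-01", tz = "UTC"), phases, seed = 1)
  expect_true(sim$truth$homed)
  # straight line due north: x stays ~0, y increases by ~500 per step
  xy <- coords(sim$track)
  expect_lt(max(abs(xy[, 1])), 5)
  steps <- stepSeries(sim$track)
  expect_equal(steps$step_length_m, rep(500, nrow(steps)), tolerance = 1e-6)
  # 11.9 km minus the 1 km stop radius at 500 m per step
  expect_equal(sim$truth$arrival_fix - 1L, ceiling((11900 - 1000) / 500))
  expect_equal(sim$truth$homing_time_days,
               (sim$truth$arrival_fix - 1) * 1800 / 86400)
})

test_that("an unbiased walk yields uniform outer-ring bearings", {
  set.seed(61)
  phases <- list(wander = phaseSpec("wander", biasWeight = 0,
                                    persistenceWeight = 0, kappa = 0,
                                    stepMeanM = 400, durationSteps = 400L))
  ev <- makeEvent(home = c(0, 11900))
  bearings <- vapply(1:120, function(i) {
    sim <- simulateTrack(c(0, 0), c(0, 11900), ev$release_time, phases,
                         seed = 6000 + i)
    rb <- ringBearing(sim$track, ev, 5000)
    if (rb$crossed) rb$home_relative_deg else NA_real_
  }, numeric(1))
  bearings <- bearings[!is.na(bearings)]
  expect_gt(length(bearings), 60)
  expect_gt(rayleighTest(bearings)$p_value, 0.01)
})

test_that("same seed gives byte-identical study output", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeStudy(suppressWarnings(simulateStudy(studySpec(seed = 99))), d1)
  writeStudy(suppressWarnings(simulateStudy(studySpec(seed = 99))), d2)
  for (f in c("telemetry.csv", "events.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  writeStudy(suppressWarnings(simulateStudy(studySpec(seed = 100))), d3)
  expect_false(identical(readLines(file.path(d1, "telemetry.csv")),
                         readLines(file.path(d3, "telemetry.csv"))))
})

test_that("the study census matches its design", {
  st <- frozenStudy(seed = 7)
  expect_equal(nrow(st$events), 35)
  expect_equal(length(st$tracks), 35)
  expect_equal(sum(st$truth$homed), 31)
  expect_equal(length(unique(st$events$animal_id)), 21)
  expect_lte(max(table(st$events$animal_id)), 3)
  expect_true(all(st$events$translocation_distance_m > 6000))
  # 30-min cadence everywhere
  for (tr in st$tracks[1:5]) {
    expect_equal(unique(diff(as.numeric(fixTimes(tr)))), 1800)
  }
})

test_that("step lengths follow the specified gamma distribution", {
  set.seed(62)
  spec <- phaseSpec("p", 0, 0, 0, stepMeanM = 150, stepShape = 4)
  x <- HomingTrack:::drawStep(spec, 20000)
  ks <- suppressWarnings(ks.test(x, "pgamma", shape = 4, scale = 150 / 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("heading noise follows the von Mises concentration", {
  set.seed(63)
  # r of a large von Mises sample estimates A(kappa) = I1/I0
  th <- HomingTrack:::rvonmises(40000, 0, 2)
  r <- meanVector(th * 180 / pi)$r
  A2 <- besselI(2, 1) / besselI(2, 0)
  expect_equal(r, A2, tolerance = 0.01)
  expect_equal(mean(sin(th)), 0, tolerance = 0.02)
  # kappa = 0 is circular-uniform
  th0 <- HomingTrack:::rvonmises(20000, 0, 0)
  expect_gt(rayleighTest(th0 * 180 / pi)$p_value, 0.01)
})

test_that("a fully biased study homes on schedule", {
  phases <- list(homing = phaseSpec("homing", biasWeight = 1,
                                    persistenceWeight = 0, kappa = 1e6,
                                    stepMeanM = 500, stepShape = Inf))
  for (seed in 1:5) {
    d <- 8100 + 2000 * seed
    sim <- simulateTrack(c(0, 0), c(0, d),
                         as.POSIXct("2021-03-01", tz = "UTC"), phases,
                         seed = seed)
    expect_true(sim$truth$homed)
    # exact-boundary geometries may slip by one step of heading jitter
    expect_lte(abs(sim$truth$arrival_fix - 1L - ceiling((d - 1000) / 500)), 1)
  }
})

test_that("geographic-mode studies survive the geodesic pipeline", {
  st <- suppressWarnings(simulateStudy(studySpec(
    nAnimals = 4L, nEvents = 5L, fractionNonHoming = 0.2,
    exploratoryMeanSteps = 24, frame = "geographic", seed = 17)))
  expect_equal(coordFrame(st$tracks[[1]]), "geographic")
  oc <- suppressWarnings(homingOutcomes(st$tracks, st$events))
  expect_equal(oc$homed, st$truth$homed)
  # homing times agree within one fix interval despite the projection
  expect_equal(oc$homing_time_days, st$truth$homing_time_days,
               tolerance = 0.03)
})
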