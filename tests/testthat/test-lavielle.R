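test_that("contrast matches hand arithmetic and the naive oracle", {
  expect_equal(segContrast(rep(3.2, 6), 1, 7), 0)
  expect_equal(segContrast(c(0, 10), 1, 3), 50)
  set.seed(41)
  y <- rnorm(50, sd = 4)
  for (rep in 1:500) {
    i <- sample(1:50, 1)
    j <- i + sample.int(51 - i, 1)
    expect_equal(segContrast(y, i, j), oracleContrastMean(y, i, j),
                 tolerance = 1e-9)
  }
})

test_that("variance-type contrasts follow their formulas", {
  y <- c(1, 2, 3, 10)
  segML <- function(v) sum((v - mean(v))^2) / length(v)
  expect_equal(segContrast(y, 1, 4, "meanvar"), 3 * log(segML(y[1:3])))
  g <- mean(y)
  expect_equal(segContrast(y, 1, 4, "var"),
               3 * log(sum((y[1:3] - g)^2) / 3))
})

test_that("the DP equals exhaustive enumeration on random series", {
  set.seed(42)
  cfg <- segmentationConfig(lmin = 2, kmax = 3)
  for (rep in 1:60) {
    y <- rnorm(12)
    op <- optimalPartitions(y, cfg)
    for (K in 1:3) {
      bf <- oracleBestPartition(y, K, 2)
      expect_equal(op$J[K], bf$J, tolerance = 1e-9)
      expect_equal(unname(op$boundariesFor(K)), unname(bf$boundaries))
    }
  }
})

test_that("J(1) is the whole-series contrast and perfect shifts give J(2) = 0", {
  set.seed(43)
  y <- rnorm(30)
  op <- optimalPartitions(y, segmentationConfig(lmin = 4, kmax = 4))
  expect_equal(op$J[1], segContrast(y, 1, 31), tolerance = 1e-12)
  y2 <- c(rep(0, 4), rep(10, 4))
  op2 <- optimalPartitions(y2, segmentationConfig(lmin = 4, kmax = 2))
  expect_equal(op2$J[2], 0)
  expect_equal(unname(op2$boundariesFor(2)), cbind(c(1L, 5L), c(5L, 9L)),
               ignore_attr = TRUE)
})

test_that("choose-K applies the normalized second-difference rule", {
  # hand evaluation: Jtilde = (4, 1.049, 1.016, 1); D(2) = 2.918, D(3) = 0.016
  res <- chooseK(c(100, 10, 9, 8.5))
  expect_equal(res$chosenK, 2L)
  expect_equal(res$D[2], 2.91803279, tolerance = 1e-6)
  expect_equal(res$D[3], 0.01639344, tolerance = 1e-6)
  # flat curve: degenerate normalization
  expect_equal(chooseK(c(5, 5, 5, 5))$chosenK, 1L)
  # strong drops at both K=2 and K=3
  expect_equal(chooseK(c(100, 40, 2, 1))$chosenK, 3L)
  # padded last-difference convention can select kmax
  expect_equal(chooseK(c(100, 60, 30, 1), padLastD = TRUE)$chosenK, 4L)
})

test_that("a two-level series is split into its two levels", {
  y <- c(rep(0, 6), rep(10, 6))
  expect_warning(sg <- segmentTrack(y, segmentationConfig(lmin = 4, kmax = 4)),
                 "kmax lowered")
  expect_equal(chosenK(sg), 2L)
  expect_equal(unname(segmentBounds(sg)), cbind(c(1L, 7L), c(7L, 13L)),
               ignore_attr = TRUE)
})

test_that("segmentation respects lmin and covers the series", {
  set.seed(44)
  for (rep in 1:30) {
    y <- rnorm(40) + rep(c(0, 3, 0, 5), each = 10) * rbinom(1, 1, 0.7)
    sg <- segmentTrack(y, segmentationConfig())
    b <- unname(segmentBounds(sg))
    expect_true(all(b[, 2] - b[, 1] >= 4))
    expect_equal(b[1, 1], 1L)
    expect_equal(b[nrow(b), 2], 41L)
    if (nrow(b) > 1) expect_equal(b[-1, 1], b[-nrow(b), 2])
  }
})

test_that("segmentation is invariant to shifting and scaling the series", {
  set.seed(45)
  y <- c(rnorm(12, 0), rnorm(12, 6), rnorm(12, 1))
  ref <- segmentTrack(y, segmentationConfig())
  shifted <- segmentTrack(y + 100, segmentationConfig())
  scaled <- segmentTrack(y * 3.7, segmentationConfig())
  expect_equal(segmentBounds(shifted), segmentBounds(ref))
  expect_equal(segmentBounds(scaled), segmentBounds(ref))
  expect_equal(chosenK(shifted), chosenK(ref))
  expect_equal(chosenK(scaled), chosenK(ref))
})

test_that("null tracks are segmented far less than structured tracks", {
  # the D(K) > 0.75 rule at kmax = 4 has limited specificity on pure-noise
  # series (D is defined at only two K values); the measured null K = 1
  # rate is ~50-60%, against ~100% K = 3 on genuinely three-phase tracks
  k1 <- 0
  for (i in 1:100) {
    tr <- makeRandomWalkTrack(n = 80, seed = 400 + i)
    if (chosenK(segmentTrack(tr)) == 1L) k1 <- k1 + 1
  }
  expect_gte(k1, 40)
  k3 <- 0
  for (i in 1:30) {
    sim <- simulateTrack(c(0, 0), c(0, 11900),
                         as.POSIXct("2021-03-01", tz = "UTC"),
                         defaultPhases(48), seed = 700 + i)
    if (chosenK(segmentTrack(sim$track)) == 3L) k3 <- k3 + 1
  }
  expect_gte(k3 / 30, 0.9)
  expect_gt(k3 / 30, (100 - k1) / 100)
})

test_that("three-phase generator tracks are recovered as K = 3", {
  phases <- defaultPhases(exploratorySteps = 60)
  sim <- simulateTrack(c(0, 0), c(0, 11900),
                       as.POSIXct("2021-03-01", tz = "UTC"), phases, seed = 9)
  sg <- segmentTrack(sim$track)
  expect_equal(chosenK(sg), 3L)
  b <- segmentBounds(sg)
  expect_lte(abs(b[2, 1] - sim$truth$phase_start_steps["homing"]), 3)
  expect_lte(abs(b[3, 1] - sim$truth$phase_start_steps["arrival"]), 3)
})

test_that("tracks starting in the homing phase come out as two segments", {
  phases <- defaultPhases()[c("homing", "arrival")]
  sim <- simulateTrack(c(0, 0), c(0, 11900),
                       as.POSIXct("2021-03-01", tz = "UTC"), phases, seed = 10)
  expect_equal(sim$truth$n_phases, 2)
  expect_equal(chosenK(segmentTrack(sim$track)), 2L)
})
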