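test_that("mean vector matches closed forms", {
  mv <- meanVector(c(30, 30, 30))
  expect_equal(mv$r, 1)
  expect_equal(mv$mean_angle_deg, 30)
  mv <- meanVector(c(0, 90))
  expect_equal(mv$r, sqrt(2) / 2)
  expect_equal(mv$mean_angle_deg, 45)
  mv <- meanVector(c(0, 180))
  expect_equal(mv$r, 0, tolerance = 1e-12)
  expect_true(is.na(mv$mean_angle_deg))
})

test_that("Rayleigh statistic and p behave at the extremes", {
  res <- rayleighTest(rep(77, 8))
  expect_equal(res$statistic, 8)
  expect_lt(res$p_value, 0.001)
  res <- rayleighTest(seq(0, 324, by = 36))  # n = 10 evenly spaced
  expect_equal(res$r, 0, tolerance = 1e-12)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_warning(rayleighTest(c(0, 10)), "n < 4")
})

test_that("Rayleigh p-values are uniform under the null", {
  set.seed(31)
  ps <- replicate(500, rayleighTest(runif(1000, 0, 360))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("directedness test handles the trivial extremes", {
  # perfectly directed, 3 clusters
  res <- manovaDirectedness(rep(10, 6), rep(1:3, each = 2), TRUE)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$mean_angle_deg, 10)
  # perfectly uniform, each bearing its own cluster
  ang <- seq(0, 315, by = 45)
  res <- manovaDirectedness(ang, seq_along(ang), TRUE)
  expect_equal(res$r, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.95)
  # pooled variant, uniform
  res <- manovaDirectedness(ang, useRandomIntercept = FALSE)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
})

test_that("fewer than five bearings refuses with insufficient_n", {
  res <- manovaDirectedness(c(0, 10, 20, 30), rep(1:2, 2), TRUE)
  expect_equal(res$status, "insufficient_n")
  expect_true(is.na(res$p_value))
})

test_that("tests are equivariant under rotation of all bearings", {
  set.seed(32)
  ang <- vonMisesDeg(14, 70, 1.5)
  cl <- rep(1:7, each = 2)
  for (shift in c(33, 140, 251)) {
    expect_equal(meanVector(wrap360(ang + shift))$mean_angle_deg,
                 wrap360(meanVector(ang)$mean_angle_deg + shift),
                 tolerance = 1e-9)
    expect_equal(rayleighTest(wrap360(ang + shift))$p_value,
                 rayleighTest(ang)$p_value, tolerance = 1e-9)
    expect_equal(manovaDirectedness(wrap360(ang + shift),
                                    useRandomIntercept = FALSE)$p_value,
                 manovaDirectedness(ang, useRandomIntercept = FALSE)$p_value,
                 tolerance = 1e-9)
    # the component-wise mixed Wald test is rotation-equivariant only to
    # fitting tolerance; require agreement on the absolute p scale
    expect_lt(abs(manovaDirectedness(wrap360(ang + shift), cl, TRUE)$p_value -
                    manovaDirectedness(ang, cl, TRUE)$p_value), 0.02)
  }
})

test_that("with one bearing per cluster the mixed test collapses to the pooled one", {
  set.seed(33)
  ang <- vonMisesDeg(18, 0, 0.8)   # weakly directed, moderate p
  mixed <- manovaDirectedness(ang, seq_along(ang), TRUE)
  pooled <- manovaDirectedness(ang, useRandomIntercept = FALSE)
  expect_equal(mixed$p_value, pooled$p_value,
               tolerance = 0.1 * max(pooled$p_value, 1e-12))
})

test_that("the mixed test has its tabulated power against a directed alternative", {
  # frozen Monte-Carlo regression: von Mises(0, kappa = 2) bearings over
  # 10 clusters x 2 with 20-degree cluster offsets give power ~0.995
  set.seed(303)
  cl <- rep(1:10, each = 2)
  rej <- 0
  for (b in 1:150) {
    off <- rnorm(10, 0, 20)
    ang <- wrap360(vonMisesDeg(20, 0, 2) + off[cl])
    if (manovaDirectedness(ang, cl, TRUE)$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 150, 0.95)
})

test_that("bootstrap CI guards and degenerate cases behave", {
  expect_error(bootstrapMeanCI(rep(5, 10), B = 1), "at least 100")
  expect_error(bootstrapMeanCI(c(1, 2, 3), B = 1000), "at least 5")
  ci <- bootstrapMeanCI(rep(42, 10), B = 200, cluster = FALSE, seed = 1)
  expect_equal(ci$ci_low_deg, 42)
  expect_equal(ci$ci_high_deg, 42)
  # r = 0: undefined
  ang <- seq(0, 315, by = 45)
  expect_warning(ci <- bootstrapMeanCI(ang, B = 200, cluster = FALSE, seed = 1),
                 "undefined")
  expect_true(is.na(ci$ci_low_deg))
})

test_that("the bootstrap CI covers a strongly directed mean", {
  set.seed(34)
  ang <- vonMisesDeg(30, 0, 10)
  ci <- bootstrapMeanCI(ang, B = 2000, cluster = FALSE, seed = 9)
  width <- wrap360(ci$ci_high_deg - ci$ci_low_deg)
  expect_lt(width, 30)
  expect_lte(wrap360(0 - ci$ci_low_deg), width)  # true mean 0 inside the arc
})
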