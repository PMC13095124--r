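test_that("modulation latency is the first crossing of 90% of the maximum", {
  expect_equal(modulationLatency(c(0, 0, 0, 0, 1, 1)), 5L)
  expect_equal(modulationLatency(rep(0.4, 8)), 1L)
  expect_equal(modulationLatency(0.1 * (1:10)), 9L)
  # invariant to positive rescaling
  s <- c(0.1, 0.3, 0.2, 0.8, 0.9, 1.0)
  expect_equal(modulationLatency(s), modulationLatency(17.3 * s))
  expect_true(is.na(modulationLatency(rep(0, 5))))
  expect_error(modulationLatency(numeric(0)), "empty")
})

test_that("the R^2 standard error follows the closed form", {
  expect_equal(r2StandardError(0, 60, 1), 0)
  expect_equal(r2StandardError(1, 60, 1), 0)
  # independent arithmetic arrangement of the same formula
  r2 <- 0.55; n <- 60; k <- 1
  want <- 2 * sqrt(r2) * (1 - r2) * (n - k - 1) / sqrt((n^2 - 1) * (n + 3))
  expect_equal(r2StandardError(r2, n, k), want)
  expect_equal(r2StandardError(r2, n, k), 0.08130002, tolerance = 1e-6)
  expect_error(r2StandardError(0.5, 3, 2), "n > k")
})

test_that("the R^2 difference test yields Z and a two-sided normal p", {
  fitA <- new("RTFit", n = 60L, k = 1L, r2 = 0.55,
              se = r2StandardError(0.55, 60, 1), coef = c(0, 1))
  fitB <- new("RTFit", n = 60L, k = 1L, r2 = 0.40,
              se = r2StandardError(0.40, 60, 1), coef = c(0, 1))
  res <- r2DifferenceTest(fitA, fitB)
  expect_gt(res$z, 0)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)))
  # identical fits: Z = 0, p = 1
  same <- r2DifferenceTest(fitA, fitA)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # Z = 1.96 corresponds to p ~ 0.05
  seNeeded <- (0.55 - 0.40) / 1.96 / sqrt(2)
  fa <- new("RTFit", n = 60L, k = 1L, r2 = 0.55, se = seNeeded, coef = 0)
  fb <- new("RTFit", n = 60L, k = 1L, r2 = 0.40, se = seNeeded, coef = 0)
  expect_equal(r2DifferenceTest(fa, fb)$z, 1.96)
  expect_equal(r2DifferenceTest(fa, fb)$p, 0.04999579, tolerance = 1e-6)
  zeroSe <- new("RTFit", n = 60L, k = 1L, r2 = 0.55, se = 0, coef = 0)
  expect_error(r2DifferenceTest(zeroSe, zeroSe), "zero standard error")
})

test_that("RT regression recovers exact fits, nulls, and filters outliers", {
  set.seed(3)
  m <- 5:44
  # affine transform, no noise: R^2 = 1
  fit <- suppressWarnings(rtRegression(m, 300 + 25 * m))
  expect_equal(fit@r2, 1)
  expect_equal(fit@n, 40L)
  # independent noise: R^2 near zero over simulations
  r2s <- replicate(30, rtRegression(m, rnorm(40, 500, 60))@r2)
  expect_lt(mean(r2s), 0.1)
  # outlier filtering on the 1/RT scale drops extreme observations
  h <- 300 + 25 * m
  h[1] <- 20  # extremely fast RT: large 1/RT deviation
  fit <- suppressWarnings(rtRegression(m, h))
  expect_equal(fit@n, 39L)
  expect_gt(fit@r2, 0.99)
  expect_error(rtRegression(1:2, 1:2), "more than 2")
})

test_that("synthetic RTs recover the generating explained variance", {
  set.seed(8)
  m <- rep(4:33, each = 10)  # 300 observations
  for (target in c(0.3, 0.7)) {
    h <- syntheticRTs(m, r2 = target, seed = 21)
    fit <- rtRegression(m, h)
    expect_lt(abs(fit@r2 - target), 0.1)
  }
  # r2 = 1 means a deterministic affine map
  expect_equal(suppressWarnings(rtRegression(m, syntheticRTs(m, 1, seed = 1)))@r2, 1)
})

test_that("model RT equals the within-object geodesic distance plus one", {
  w <- chainWeights()
  set.seed(4)
  rts <- integer(0); geos <- integer(0)
  for (s in c(2, 5, 9, 12, 31)) {
    o <- generateObjectPair(12, rngSeed = s, areaRange = c(6, 20))
    gates <- cellGate(rbind(o@target, o@distractor), 12L, nScales = 1L)
    rt <- modelRT(w, gates, o, tMax = 40)
    geo <- geodesicDistance(o)
    expect_equal(rt, geo + 1L)
    rts <- c(rts, rt); geos <- c(geos, geo)
  }
  # non-decreasing in geodesic distance across the battery
  expect_true(all(diff(rts[order(geos)]) >= 0))
})

test_that("an untrained network shows no systematic enhancement at probes", {
  w <- newRecurrentWeights(4, zero = TRUE)
  gwz <- newGateWeights(4, seed = 1)  # untrained gates: silent
  tab <- gapEffect(w, gwz, seeds = 1, narrow = 1, wide = 8, tMax = 10)
  expect_true(all(is.na(tab$latency)))
})
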