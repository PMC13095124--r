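test_that("theta clips to the unit interval and phi saturates from zero", {
  expect_equal(thetaClip(c(-0.5, 0.4, 1.7)), c(0, 0.4, 1))
  expect_equal(phiGate(0), 0)
  expect_equal(phiGate(0.01), 1 / sqrt(2))
  expect_equal(phiGate(0.3), 30 / sqrt(1 + 900))  # ~0.99944
  expect_equal(phiGate(-0.01), 1 / sqrt(2))       # even in x
  x <- seq(0, 0.3, by = 0.01)
  expect_true(all(diff(phiGate(x)) >= 0))         # monotone in |x|
  # the alternative non-monotone reading peaks and falls off
  expect_lt(phiGate(0.3, bump = TRUE), phiGate(0.01, bump = TRUE))
})

test_that("a zero stimulus collapses to the all-zero fixed point at t = 1", {
  w <- newRecurrentWeights(2, seed = 1)
  img <- array(0, c(9, 9, 3))
  gates <- randomGates(9, 2)
  st <- runToFixedPoint(img, gates, w)
  expect_true(isConverged(st))
  expect_equal(convergenceTime(st), 1L)
  for (y in st@Y) expect_true(all(y == 0))
})

test_that("enhancement advances exactly one cell per step along the curve", {
  len <- 7L
  s <- straightCurveStimulus(len, gridSize = 12L)
  w <- chainWeights()
  gates <- cellGate(s@target, 12L, nScales = 1L)
  st <- runToFixedPoint(s, gates, w, tMax = 30, record = TRUE)
  expect_true(isConverged(st))
  # at time t, exactly the first t cells of the target curve are enhanced
  for (t in seq_len(len)) {
    y1 <- st@history[[min(t, length(st@history))]][[2]][, , 1]
    on <- which(y1 > 0, arr.ind = TRUE)
    want <- s@target[seq_len(min(t, len)), , drop = FALSE]
    expect_equal(on[order(on[, 2]), , drop = FALSE],
                 want[order(want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
  # converged enhancement covers the whole target curve and nothing else
  yT <- st@Y[[2]][, , 1]
  expect_true(all(yT[s@target] > 0))
  expect_equal(sum(yT > 0), len)
  # latency grows by one per cell along the curve; the cue cell itself is
  # boosted once more when disinhibition returns from its neighbor at t = 3
  lat <- vapply(seq_len(len), function(i) {
    series <- vapply(st@history, function(h) h[[2]][s@target[i, 1], s@target[i, 2], 1],
                     numeric(1))
    modulationLatency(series)
  }, integer(1))
  expect_equal(lat, c(3L, seq(2L, len)))
})

test_that("gating hard-off keeps enhancement out of ungated cells", {
  s <- straightCurveStimulus(7L, gridSize = 12L)
  w <- chainWeights()
  # open the gate only over the first 4 cells
  gates <- cellGate(s@target[1:4, ], 12L, nScales = 1L)
  st <- runToFixedPoint(s, gates, w, tMax = 30)
  yT <- st@Y[[2]][, , 1]
  expect_true(all(yT[s@target[1:4, , drop = FALSE]] > 0))
  expect_true(all(yT[s@target[5:7, , drop = FALSE]] == 0))
})

test_that("activity is bounded by the gated feedforward drive and never diverges", {
  set.seed(42)
  for (rep in 1:25) {
    L <- sample(1:3, 1)
    H <- 27L
    w <- newRecurrentWeights(L)
    # random rescaling, including aggressive weights
    k <- w@kernels
    k$ff2 <- lapply(k$ff2, function(a) a * runif(1, 0.5, 8))
    hm <- lapply(k$hor, function(a) a * runif(1, 0.5, 8))
    for (l in seq_along(hm)) {
      hm[[l]][!horizontalMask(dim(hm[[l]])[3], dim(hm[[l]])[4])] <- 0
      k$hor[[l]] <- hm[[l]]
    }
    k$fb <- lapply(k$fb, function(a) a * runif(1, 0.5, 8))
    w <- methods::initialize(w, kernels = k)
    img <- array(runif(H * H * 3) * (runif(H * H * 3) < 0.3), c(H, H, 3))
    gates <- randomGates(H, L)
    st <- runToFixedPoint(img, gates, w, tMax = 30)
    phiX <- phiGate(img)
    for (l in seq_len(L)) {
      # feedforward drive from the layer below at the final state
      drive <- oracleConv3s3(st@Y[[l]], w@kernels$ff2[[l]])
      phiG <- phiGate(gates[[l]])
      bound <- array(apply(drive, 3, function(m) phiG * m), dim(drive))
      expect_true(all(st@Y[[l + 1]] <= pmax(bound, 0) + 1e-12))
      # hard-off: zero gate implies zero activity
      for (c in seq_len(dim(st@Y[[l + 1]])[3]))
        expect_true(all(st@Y[[l + 1]][, , c][phiG == 0] == 0))
    }
    for (y in st@Y) expect_true(all(is.finite(y)))
  }
})

test_that("without the red cue a symmetric stimulus yields no differential enhancement", {
  # mirror-symmetric pair of straight curves, cue channel removed
  s <- straightCurveStimulus(7L, gridSize = 12L, row = 4L)
  img <- s@image
  img[, , 1] <- 0  # strip the red cue
  img[, , 3] <- 0  # and the markers
  img[, , 2] <- pmax(img[, , 2], apply(img, c(1, 2), max))
  w <- chainWeights()
  gates <- cellGate(rbind(s@target, s@distractor), 12L, nScales = 1L)
  st <- runToFixedPoint(img, gates, w, tMax = 30)
  yT <- st@Y[[2]][, , 1]
  expect_equal(yT[s@target], yT[s@distractor])
})

test_that("interneuron populations stay in their defined ranges", {
  set.seed(7)
  w <- newRecurrentWeights(2, seed = 3)
  img <- array(runif(27 * 27 * 3, 0, 1), c(27, 27, 3))
  gates <- randomGates(27, 2)
  st <- runToFixedPoint(img, gates, w, tMax = 30)
  for (v in st@VIP) { expect_gte(min(v), 0); expect_lte(max(v), 1) }
  for (s2 in st@SOM) { expect_gte(min(s2), 0); expect_lte(max(s2), 1) }
  for (y in st@Y) expect_gte(min(y), 0)
})
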