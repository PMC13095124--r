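test_that("the Q readout matches a loop-based transposed-convolution oracle", {
  set.seed(11)
  w <- newRecurrentWeights(2, seed = 4)
  img <- array(runif(9 * 9 * 3) * (runif(9 * 9 * 3) < 0.5), c(9, 9, 3))
  gates <- randomGates(9, 2, density = 0.9)
  st <- runToFixedPoint(img, gates, w)
  q <- computeQMap(st, w, warn = FALSE)
  expect_equal(unclass(q), oracleQMap(st@Y, w@kernels), tolerance = 1e-12,
               ignore_attr = TRUE)
  # all-zero state reads out an identically zero map (zero-bias readout)
  z <- zeroState(img, w)
  expect_true(all(computeQMap(z, w, warn = FALSE) == 0))
})

test_that("readout is local to each unit's receptive-field footprint", {
  w <- newRecurrentWeights(2, seed = 5)
  img <- array(0, c(9, 9, 3))
  z <- zeroState(img, w)
  # one active unit in layer 2 projects only inside its 9x9 pixel footprint
  z@Y[[3]][1, 1, 2] <- 1
  q <- computeQMap(z, w, warn = FALSE)
  expect_true(any(q[1:9, 1:9] != 0))
  q[1:9, 1:9] <- 0
  expect_true(all(q == 0))
})

test_that("action selection is greedy, tie-broken, and Boltzmann under exploration", {
  q <- matrix(c(0.2, 0.9, 0.9, 0.1), 2, 2)
  sel <- selectAction(q, epsilon = 0, rngSeed = 1)
  # ties broken towards the lowest linear (column-major storage) index
  expect_equal(sel$action, c(2, 1))
  expect_equal(sel$qa, 0.9)
  expect_true(sel$greedy)
  # analytic two-pixel softmax: Q = (ln 2, 0) -> P = (2/3, 1/3)
  p <- boltzmannProbs(matrix(c(log(2), 0), 1, 2))
  expect_equal(as.vector(p), c(2 / 3, 1 / 3))
  expect_equal(sum(boltzmannProbs(matrix(rnorm(100), 10, 10))), 1)
  # constant map: empirical frequencies uniform within 3 sigma
  qc <- matrix(1, 2, 2)
  withr_seed <- 99
  counts <- integer(4)
  set.seed(withr_seed)
  for (i in 1:4000) {
    a <- selectAction(qc, epsilon = 1)
    counts[a$action[1] + 2 * (a$action[2] - 1)] <-
      counts[a$action[1] + 2 * (a$action[2] - 1)] + 1
  }
  expect_true(all(abs(counts - 1000) < 3 * sqrt(4000 * 0.25 * 0.75)))
})

test_that("reward and prediction error follow the task rule", {
  s <- generateCurvePair(36, 5, rngSeed = 2)
  hitPx <- (s@targetCell - 1) * 3 + 2
  missPx <- (s@distractorCell - 1) * 3 + 2
  r <- rewardSignal(hitPx, s, qa = 0.8)
  expect_equal(r$r, 1); expect_equal(r$delta, 0.2)
  r <- rewardSignal(missPx, s, qa = 0.8)
  expect_equal(r$r, 0); expect_equal(r$delta, -0.8)
  # a perfectly predicted reward leaves no update drive
  expect_equal(rewardSignal(hitPx, s, qa = 1)$delta, 0)
  # any pixel of the 3x3 target block counts
  for (dr in 0:2) for (dc in 0:2)
    expect_equal(rewardSignal((s@targetCell - 1) * 3 + 1 + c(dr, dc), s, 0)$r, 1)
})
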