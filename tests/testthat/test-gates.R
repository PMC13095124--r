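test_that("the gate forward pass matches a naive loop evaluation", {
  set.seed(2)
  for (rep in 1:4) {
    gw <- newGateWeights(2, seed = rep)
    H <- 9L
    img <- array(runif(H * H * 3) * (runif(H * H * 3) < 0.5), c(H, H, 3))
    gs <- gateForward(img, gw)
    want <- oracleGateForward(img, gw)
    for (l in 1:2)
      expect_equal(gs@xgate[[l]], want[[l]], tolerance = 1e-12)
  }
})

test_that("gate outputs obey the sigmoid-shift closed forms", {
  gw <- newGateWeights(2, seed = 1)
  # zero image, zero biases: sigmoid(0) = 0.5 < 0.7, all gates silent
  gs <- gateForward(array(0, c(27, 27, 3)), gw)
  for (g in gs@xgate) expect_true(all(g == 0))
  # pre-sigmoid activation exactly logit(0.7) sits on the gate boundary
  expect_equal(max(0, 1 / (1 + exp(-log(0.7 / 0.3))) - 0.7), 0)
  # gates never exceed 0.3, and gate > 0 iff sigmoid > 0.7
  gw2 <- trainedCurveGates()
  s <- generateCurvePair(36, 7, rngSeed = 404)
  gs2 <- gateForward(s, gw2)
  for (l in seq_along(gs2@xgate)) {
    expect_lte(max(gs2@xgate[[l]]), 0.3)
    expect_equal(gs2@xgate[[l]] > 0, gs2@sig[[l]] > 0.7)
  }
  # dimensions match the hidden layers on the padded canvas
  expect_equal(vapply(gs2@xgate, nrow, integer(1)), 162L %/% 3L^(1:4))
})

test_that("trained curve gates reach high accuracy on held-out stimuli", {
  gw <- trainedCurveGates()
  stimuli <- lapply(1:100, function(i)
    generateCurvePair(36, sample(3:12, 1), rngSeed = 5e5 + i))
  acc <- gateAccuracy(gw, stimuli)
  # the fine scales are essentially perfect; the coarse scales see only a
  # handful of positive examples at desk-scale training sizes (the
  # full-scale study trains every scale past 99%; see the methods vignette)
  expect_true(all(acc[1:2] >= 0.99))
  expect_true(all(acc >= 0.90))
})

test_that("trained curve gates discriminate ambiguous from valid receptive fields", {
  gw <- trainedCurveGates()
  # adversarial set: narrow bottlenecks force scale-2 RFs that straddle
  # both curves; a working detector opens on valid straight runs and stays
  # mostly shut on straddles (the full-scale study drives the straddle
  # false-positive rate to zero)
  fp <- 0L; nAmb <- 0L; hit <- 0L; nPos <- 0L
  for (s in 1:6) {
    bp <- generateBottleneckPair(1, rngSeed = 900 + s)
    st <- bp$stimulus
    lab <- gateLabelsCurve(st, 4)
    gs <- gateForward(st, gw)
    G <- tracenet:::paddedGridSize(st, 4)
    inT <- matrix(FALSE, G, G); inT[st@target] <- TRUE
    inD <- matrix(FALSE, G, G); inD[st@distractor] <- TRUE
    for (l in 1:2) {
      b <- 3L^(l - 1L); nb <- G %/% b
      for (bi in seq_len(nb)) for (bj in seq_len(nb)) {
        rows <- ((bi - 1) * b + 1):(bi * b)
        cols <- ((bj - 1) * b + 1):(bj * b)
        open <- gs@xgate[[l]][bi, bj] > 0
        if (any(inT[rows, cols]) && any(inD[rows, cols])) {
          nAmb <- nAmb + 1L
          if (open) fp <- fp + 1L
        } else if (lab@labels[[l]][bi, bj]) {
          nPos <- nPos + 1L
          if (open) hit <- hit + 1L
        }
      }
    }
  }
  expect_gt(nAmb, 0)
  expect_gt(hit / nPos - fp / nAmb, 0.5)
})

test_that("gates over high-curvature bends are silent at coarse scales", {
  gw <- trainedCurveGates()
  # L-bend centered in an aligned scale-2 block
  target <- rbind(c(13, 13), c(13, 14), c(13, 15), c(14, 15), c(15, 15))
  distractor <- cbind(30, 13:17)
  s <- tracenet:::newStimulus(36L, "curve", target, distractor,
                              fixationCell = target[1, ],
                              targetCell = target[5, ],
                              distractorCell = distractor[5, ], seed = 0L)
  gs <- gateForward(s, gw)
  expect_equal(gs@xgate[[2]][5, 5], 0)  # block rows 13-15, cols 13-15
})

test_that("scale usage reports the coarsest active gate and arrival times", {
  s <- straightCurveStimulus(7L, gridSize = 12L)
  w <- chainWeights()
  gates <- new("GateStack", x0 = matrix(0, 0, 0), xint = list(),
               sig = list(), xgate = cellGate(s@target, 12L, nScales = 1L))
  st <- runToFixedPoint(s, gates@xgate, w, record = TRUE)
  usage <- scaleUsageMap(st, gates, s)
  expect_equal(usage$scale, rep(1L, 7))
  expect_equal(usage$latency, c(3L, 2:7))
  # a gate stack that is silent above scale 1 forces scale-1 everywhere
  expect_true(all(usage$scale == 1L))
})
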