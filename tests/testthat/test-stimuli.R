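test_that("curve pairs are reproducible, self-avoiding and well separated", {
  for (s in c(3, 17, 101)) {
    a <- generateCurvePair(36, 7, rngSeed = s)
    b <- generateCurvePair(36, 7, rngSeed = s)
    expect_identical(a@image, b@image)
    # self-avoidance and 4-connectivity along each curve
    for (cur in list(a@target, a@distractor)) {
      expect_false(any(duplicated(cur)))
      steps <- abs(diff(cur[, 1])) + abs(diff(cur[, 2]))
      expect_true(all(steps == 1))
    }
    # inter-curve separation of at least one empty cell
    cheb <- outer(seq_len(nrow(a@target)), seq_len(nrow(a@distractor)),
                  Vectorize(function(i, j) max(abs(a@target[i, ] - a@distractor[j, ]))))
    expect_gte(min(cheb), 2)
  }
  # different seeds give different stimuli
  imgs <- lapply(1:20, function(s) generateCurvePair(36, 5, rngSeed = s)@image)
  expect_gt(length(unique(lapply(imgs, c))), 15)
})

test_that("rendered images round-trip the generating geometry", {
  s <- generateCurvePair(36, 9, rngSeed = 5)
  ec <- extractCells(s@image)
  want <- matrix(FALSE, 36, 36)
  want[rbind(s@target, s@distractor)] <- TRUE
  expect_identical(ec$figure, want)
  expect_equal(as.integer(ec$cue), s@fixationCell)
  markers <- ec$markers[order(ec$markers[, 1], ec$markers[, 2]), , drop = FALSE]
  wantM <- rbind(s@targetCell, s@distractorCell)
  wantM <- wantM[order(wantM[, 1], wantM[, 2]), ]
  expect_equal(unname(markers), unname(wantM))
  # image dimensions: grid cells render as 3x3 pixel blocks
  expect_equal(dim(s@image), c(108, 108, 3))
})

test_that("tiny grids admit only valid placements", {
  # on a 4x4 grid with 2-cell curves, enumerate every legal pair by brute
  # force and check each generated pair is one of them
  cells <- expand.grid(r = 1:4, c = 1:4)
  pairs <- list()
  for (i in seq_len(16)) for (j in seq_len(16)) {
    if (abs(cells$r[i] - cells$r[j]) + abs(cells$c[i] - cells$c[j]) == 1)
      pairs[[length(pairs) + 1L]] <- rbind(unlist(cells[i, ]), unlist(cells[j, ]))
  }
  valid <- function(a, b) {
    cheb <- outer(1:2, 1:2, Vectorize(function(i, j) max(abs(a[i, ] - b[j, ]))))
    min(cheb) >= 2
  }
  for (s in 1:10) {
    st <- generateCurvePair(4, 2, rngSeed = s)
    expect_true(valid(st@target, st@distractor))
    inEnum <- function(m) any(vapply(pairs, function(p)
      all(p == unname(m)), logical(1)))
    expect_true(inEnum(st@target))
    expect_true(inEnum(st@distractor))
  }
  # impossible placements raise a generation error
  expect_error(generateCurvePair(2, 2, rngSeed = 1), "failed to place")
})

test_that("bottleneck pairs have the requested gap and matched probes", {
  for (s in 1:3) for (gap in c(1L, 4L, 8L)) {
    bp <- generateBottleneckPair(gap, rngSeed = s)
    t <- bp$stimulus@target; d <- bp$stimulus@distractor
    cheb <- outer(seq_len(nrow(t)), seq_len(nrow(d)),
                  Vectorize(function(i, j) max(abs(t[i, ] - d[j, ]))))
    expect_equal(min(cheb), gap)
    # probes lie on the target curve, near before far along the curve
    onT <- function(cell) any(t[, 1] == cell[1] & t[, 2] == cell[2])
    expect_true(onT(bp$spec@probeNear))
    expect_true(onT(bp$spec@probeFar))
    iNear <- which(t[, 1] == bp$spec@probeNear[1] & t[, 2] == bp$spec@probeNear[2])
    iFar <- which(t[, 1] == bp$spec@probeFar[1] & t[, 2] == bp$spec@probeFar[2])
    expect_lt(iNear, iFar)
  }
  # determinism and narrow < wide by construction
  expect_identical(generateBottleneckPair(2, rngSeed = 7)$stimulus@image,
                   generateBottleneckPair(2, rngSeed = 7)$stimulus@image)
  expect_error(generateBottleneckPair(20, rngSeed = 1, farDist = 9))
})

test_that("wide-gap RFs at scales up to the gap never straddle both curves", {
  bp <- generateBottleneckPair(8, rngSeed = 2)
  s <- bp$stimulus
  G <- tracenet:::paddedGridSize(s, 4)
  inT <- matrix(FALSE, G, G); inT[s@target] <- TRUE
  inD <- matrix(FALSE, G, G); inD[s@distractor] <- TRUE
  # exhaustive RF coverage check at scales 1 and 2 (RF side 1 and 3 <= gap)
  for (l in 1:2) {
    b <- 3L^(l - 1L); nb <- G %/% b
    for (bi in seq_len(nb)) for (bj in seq_len(nb)) {
      rows <- ((bi - 1) * b + 1):(bi * b); cols <- ((bj - 1) * b + 1):(bj * b)
      expect_false(any(inT[rows, cols]) && any(inD[rows, cols]))
    }
  }
})

test_that("object pairs are disjoint, 4-connected and hold cue plus markers", {
  floodFill <- function(cells, n) {
    m <- matrix(FALSE, n, n); m[cells] <- TRUE
    seen <- matrix(FALSE, n, n)
    q <- cells[1, , drop = FALSE]; seen[q] <- TRUE
    while (nrow(q)) {
      nxt <- NULL
      for (i in seq_len(nrow(q))) {
        nb <- tracenet:::vnNeighbors(q[i, 1], q[i, 2], n)
        nb <- nb[m[nb] & !seen[nb], , drop = FALSE]
        if (nrow(nb)) { seen[nb] <- TRUE; nxt <- rbind(nxt, nb) }
      }
      q <- if (is.null(nxt)) matrix(0L, 0, 2) else nxt
    }
    sum(seen)
  }
  for (s in 1:3) {
    o <- generateObjectPair(72, rngSeed = s)
    expect_identical(o@image, generateObjectPair(72, rngSeed = s)@image)
    key <- function(m) paste(m[, 1], m[, 2])
    expect_length(intersect(key(o@target), key(o@distractor)), 0)
    # flood fill from one cell reaches the whole mask (4-connected)
    expect_equal(floodFill(o@target, 72), nrow(o@target))
    expect_equal(floodFill(o@distractor, 72), nrow(o@distractor))
    onObj <- function(cell, m) any(m[, 1] == cell[1] & m[, 2] == cell[2])
    expect_true(onObj(o@fixationCell, o@target))
    expect_true(onObj(o@targetCell, o@target))
    expect_true(onObj(o@distractorCell, o@distractor))
  }
  expect_error(generateObjectPair(72, areaRange = c(1, 5)),
               "exceed one cell")
})

test_that("curve gate labels implement straight single-curve runs", {
  # hand-built L-bend: scale-2 RF over the bend must be negative
  target <- rbind(c(4, 4), c(4, 5), c(4, 6), c(5, 6), c(6, 6))
  distractor <- rbind(c(10, 4), c(10, 5), c(10, 6), c(10, 7), c(10, 8))
  s <- tracenet:::newStimulus(12L, "curve", target, distractor,
                              fixationCell = target[1, ],
                              targetCell = target[5, ],
                              distractorCell = distractor[5, ], seed = 0L)
  lab <- gateLabelsCurve(s, 2)
  # scale 1: exactly the curve cells are positive
  expect_equal(sum(lab@labels[[1]]), nrow(target) + nrow(distractor))
  expect_true(all(lab@labels[[1]][rbind(target, distractor)]))
  # scale 2 block (2,2) covers cells rows 4-6, cols 4-6: the full bend
  expect_false(lab@labels[[2]][2, 2])
  # straight 3-cell distractor run in block (4,2) (rows 10-12, cols 4-6)
  expect_true(lab@labels[[2]][4, 2])
  # brute-force check of every scale-2 block against an exact line fit
  G <- tracenet:::paddedGridSize(s, 2)
  inT <- matrix(FALSE, G, G); inT[target] <- TRUE
  inD <- matrix(FALSE, G, G); inD[distractor] <- TRUE
  for (bi in 1:(G %/% 3)) for (bj in 1:(G %/% 3)) {
    rows <- ((bi - 1) * 3 + 1):(bi * 3); cols <- ((bj - 1) * 3 + 1):(bj * 3)
    t <- which(inT[rows, cols], arr.ind = TRUE)
    d <- which(inD[rows, cols], arr.ind = TRUE)
    cells <- rbind(t, d)
    want <- nrow(cells) > 0 && (nrow(t) == 0 || nrow(d) == 0)
    if (want) {
      onLine <- (length(unique(cells[, 1])) == 1 &&
                   all(diff(sort(cells[, 2])) == 1)) ||
                (length(unique(cells[, 2])) == 1 &&
                   all(diff(sort(cells[, 1])) == 1))
      want <- onLine
    }
    expect_equal(lab@labels[[2]][bi, bj], want)
  }
})

test_that("label resolutions match the hidden layers for all tested sizes", {
  for (px in c(108L, 144L)) {
    g <- px %/% 3L
    s <- generateCurvePair(g, 5, rngSeed = 1)
    lab <- gateLabelsCurve(s, 4)
    pad <- as.integer(ceiling(px / 81) * 81)
    expect_equal(vapply(lab@labels, nrow, integer(1)), pad %/% 3L^(1:4))
  }
  o <- generateObjectPair(198L, rngSeed = 1, areaRange = c(200L, 900L))
  lab <- gateLabelsObject(o, 4)
  expect_equal(vapply(lab@labels, nrow, integer(1)), 648L %/% 3L^(1:4))
})

test_that("object gate labels require full single-object coverage", {
  target <- as.matrix(expand.grid(4:9, 4:9))       # 6x6 solid block
  distractor <- as.matrix(expand.grid(13:15, 4:8))
  s <- tracenet:::newStimulus(18L, "object", target, distractor,
                              fixationCell = c(4, 4), targetCell = c(9, 9),
                              distractorCell = c(13, 4), seed = 0L)
  lab <- gateLabelsObject(s, 2)
  # scale 2 blocks fully inside the 6x6 object: rows 4-9 x cols 4-9 contains
  # the aligned block rows 4-6 x cols 4-6 etc.
  expect_true(lab@labels[[2]][2, 2])
  expect_true(lab@labels[[2]][3, 3])
  # any block touching background is negative
  expect_false(lab@labels[[2]][1, 1])
  # all-background block is negative
  expect_false(lab@labels[[2]][6, 6])
  # scale 1: positives are exactly the object cells
  expect_equal(sum(lab@labels[[1]]), nrow(target) + nrow(distractor))
})

test_that("stimuli survive a PNG + JSON round trip", {
  s <- generateCurvePair(36, 6, rngSeed = 3)
  path <- tempfile("stim")
  saveStimulus(s, path)
  s2 <- readStimulus(path)
  expect_equal(s2@image, s@image, tolerance = 1 / 255)
  expect_identical(s2@target, s@target)
  expect_identical(s2@fixationCell, s@fixationCell)
})
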