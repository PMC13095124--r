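#' @include utils.R
NULL

# --- low-level geometry helpers ----------------------------------------------

# 4-connected neighbors of (r, c) inside an n x n grid.
vnNeighbors <- function(r, c, n) {
  out <- cbind(r + c(-1L, 1L, 0L, 0L), c + c(0L, 0L, -1L, 1L))
  out[out[, 1] >= 1L & out[, 1] <= n & out[, 2] >= 1L & out[, 2] <= n, ,
      drop = FALSE]
}

# Self-avoiding 4-connected walk of `len` cells avoiding `forbidden` (logical
# matrix); depth-first with backtracking, bounded by `budget` node expansions.
# Returns an n x 2 matrix or NULL.
selfAvoidingWalk <- function(n, len, forbidden, budget = 4000L) {
  free <- which(!forbidden, arr.ind = TRUE)
  if (nrow(free) == 0) return(NULL)
  start <- free[sample.int(nrow(free), 1L), ]
  path <- matrix(0L, len, 2)
  path[1, ] <- start
  used <- forbidden
  used[start[1], start[2]] <- TRUE
  expansions <- 0L
  recurse <- function(depth) {
    if (depth == len) return(TRUE)
    expansions <<- expansions + 1L
    if (expansions > budget) return(FALSE)
    nb <- vnNeighbors(path[depth, 1], path[depth, 2], n)
    nb <- nb[sample.int(nrow(nb)), , drop = FALSE]
    for (i in seq_len(nrow(nb))) {
      r <- nb[i, 1]; c <- nb[i, 2]
      if (used[r, c]) next
      path[depth + 1L, ] <<- c(r, c)
      used[r, c] <<- TRUE
      if (recurse(depth + 1L)) return(TRUE)
      used[r, c] <<- FALSE
    }
    FALSE
  }
  if (recurse(1L)) path else NULL
}

# Chebyshev dilation of a cell set by 1 (cells plus their 8-neighborhood).
dilateCells <- function(cells, n) {
  m <- matrix(FALSE, n, n)
  for (dr in -1:1) for (dc in -1:1) {
    r <- cells[, 1] + dr; c <- cells[, 2] + dc
    ok <- r >= 1 & r <= n & c >= 1 & c <= n
    m[cbind(r[ok], c[ok])] <- TRUE
  }
  m
}

# Render grid geometry to an RGB pixel image.  Figure cells green, fixation
# red, markers blue; every cell is a cellPx x cellPx block.
renderStimulus <- function(n, figures, fixationCell, markerCells,
                           cellPx = 3L) {
  grid <- array(0, c(n, n, 3))
  for (f in figures) grid[cbind(f[, 1], f[, 2], 2L)] <- 1
  for (m in markerCells) {
    grid[m[1], m[2], ] <- c(0, 0, 1)
  }
  grid[fixationCell[1], fixationCell[2], ] <- c(1, 0, 0)
  expandCells(grid, cellPx)
}

newStimulus <- function(n, task, target, distractor, fixationCell, targetCell,
                        distractorCell, seed, cellPx = 3L) {
  img <- renderStimulus(n, list(target, distractor), fixationCell,
                        list(targetCell, distractorCell), cellPx)
  new("Stimulus", image = img, gridSize = as.integer(n),
      cellPx = as.integer(cellPx), task = task,
      target = target, distractor = distractor,
      fixationCell = as.integer(fixationCell),
      targetCell = as.integer(targetCell),
      distractorCell = as.integer(distractorCell), seed = as.integer(seed))
}

# --- curve-tracing stimuli ---------------------------------------------------

#' Generate a curve-tracing stimulus
#'
#' Two self-avoiding 4-connected random curves of `length` cells on a
#' `gridSize` x `gridSize` grid, kept at least one empty cell apart
#' (Chebyshev separation >= 2).  A red cue marks one end of the target curve;
#' blue markers sit on the free end of the target and on one end of the
#' distractor.  Each cell renders as a 3x3 pixel block.
#'
#' @param gridSize grid side in cells (36 in the task of record).
#' @param length curve length in cells (>= 2).
#' @param rngSeed integer seed; the same seed reproduces the stimulus
#'   bit-identically.
#' @param maxTries placement retries before giving up.
#' @return a [Stimulus-class].
#' @export
generateCurvePair <- function(gridSize = 36L, length = 7L, rngSeed = NULL,
                              maxTries = 200L) {
  n <- as.integer(gridSize)
  len <- as.integer(length)
  stopifnot(len >= 2L, len <= n * n / 2)
  withSeed(rngSeed, {
    for (try in seq_len(maxTries)) {
      a <- selfAvoidingWalk(n, len, matrix(FALSE, n, n))
      if (is.null(a)) next
      b <- selfAvoidingWalk(n, len, dilateCells(a, n))
      if (is.null(b)) next
      if (runif(1) < 0.5) a <- a[rev(seq_len(len)), , drop = FALSE]
      if (runif(1) < 0.5) b <- b[rev(seq_len(len)), , drop = FALSE]
      return(newStimulus(n, "curve", a, b,
                         fixationCell = a[1, ], targetCell = a[len, ],
                         distractorCell = b[len, ],
                         seed = if (is.null(rngSeed)) NA_integer_ else rngSeed))
    }
    stop("failed to place two curves of length ", len, " on a ", n, "x", n,
         " grid after ", maxTries, " attempts")
  })
}

#' Bottleneck stimulus specification
#'
#' @slot gapCells integer, curve separation (in cells) at the bottleneck.
#' @slot probeNear,probeFar length-2 integer target-curve cells before and
#'   behind the bottleneck.
#' @exportClass BottleneckSpec
setClass("BottleneckSpec", representation(
  gapCells = "integer", probeNear = "integer", probeFar = "integer"))

setMethod("show", "BottleneckSpec", function(object) {
  cat(sprintf("BottleneckSpec: gap %d cells; probes (%d,%d) / (%d,%d)\n",
              object@gapCells, object@probeNear[1], object@probeNear[2],
              object@probeFar[1], object@probeFar[2]))
})

#' Generate a bottleneck stimulus pair
#'
#' A straight target curve with the cue on one end and a distractor running
#' parallel at `farDist` cells that approaches to `gapCells` inside a central
#' bottleneck window, then diverges again.  Probe cells on the target curve
#' before and behind the bottleneck are recorded for latency analyses.
#'
#' @param gapCells curve separation at the bottleneck (>= 1).
#' @param rngSeed integer seed (randomizes position and left/right cue side).
#' @param gridSize grid side in cells.
#' @param farDist separation away from the bottleneck (default 9 cells).
#' @param curveLen target curve length in cells (default 27).
#' @param windowLen bottleneck window length in cells (default 7).
#' @return list with elements `stimulus` ([Stimulus-class]) and `spec`
#'   ([BottleneckSpec-class]).
#' @export
generateBottleneckPair <- function(gapCells, rngSeed = NULL, gridSize = 36L,
                                   farDist = 9L, curveLen = 27L,
                                   windowLen = 7L) {
  gapCells <- as.integer(gapCells)
  stopifnot(gapCells >= 1L, gapCells <= farDist)
  n <- as.integer(gridSize)
  if (farDist + 3L > n || curveLen + 2L > n)
    stop("bottleneck geometry does not fit on a ", n, "x", n, " grid")
  withSeed(rngSeed, {
    row0 <- sample((farDist + 2L):(n - 2L), 1L)
    col0 <- sample.int(n - curveLen + 1L, 1L)
    cols <- col0:(col0 + curveLen - 1L)
    target <- cbind(row0, cols)
    # distractor row profile: farDist outside the window, gapCells inside,
    # with 4-connected vertical transitions
    mid <- col0 + curveLen %/% 2L
    w0 <- mid - windowLen %/% 2L
    w1 <- w0 + windowLen - 1L
    prof <- integer(0)
    dist <- integer(0)
    d <- farDist
    for (cc in cols) {
      # horizontal step into this column, then vertical run to the profile
      prof <- c(prof, cc); dist <- c(dist, d)
      dWant <- if (cc >= w0 && cc <= w1) gapCells else farDist
      while (d != dWant) {
        d <- d + as.integer(sign(dWant - d))
        prof <- c(prof, cc); dist <- c(dist, d)
      }
    }
    distractor <- cbind(row0 - dist, prof)
    storage.mode(distractor) <- "integer"
    cueLeft <- runif(1) < 0.5
    if (!cueLeft) {
      target <- target[rev(seq_len(nrow(target))), , drop = FALSE]
      distractor <- distractor[rev(seq_len(nrow(distractor))), , drop = FALSE]
    }
    nearIdx <- max(2L, round(nrow(target) * 0.2))
    farIdx <- min(nrow(target) - 1L, round(nrow(target) * 0.85))
    stim <- newStimulus(n, "curve", target, distractor,
                        fixationCell = target[1, ],
                        targetCell = target[nrow(target), ],
                        distractorCell = distractor[nrow(distractor), ],
                        seed = if (is.null(rngSeed)) NA_integer_ else rngSeed)
    list(stimulus = stim,
         spec = new("BottleneckSpec", gapCells = gapCells,
                    probeNear = as.integer(target[nearIdx, ]),
                    probeFar = as.integer(target[farIdx, ])))
  })
}

# --- object-parsing stimuli --------------------------------------------------

# Region-grown 4-connected polyomino of `area` cells within the allowed mask.
# Frontier cells with more in-region neighbors are strongly preferred, which
# yields compact blobs with large homogeneous interiors (ragged growth would
# leave no RF at coarse scales fully covered).
growRegion <- function(n, area, allowed) {
  free <- which(allowed, arr.ind = TRUE)
  if (nrow(free) == 0) return(NULL)
  start <- free[sample.int(nrow(free), 1L), , drop = FALSE]
  cells <- matrix(0L, area, 2)
  cells[1, ] <- start
  inReg <- matrix(FALSE, n, n)
  inReg[start] <- TRUE
  cnt <- matrix(0L, n, n)        # in-region neighbor counts
  onFront <- matrix(FALSE, n, n)
  frontier <- matrix(0L, 0, 2)
  addCellEffects <- function(cell) {
    nb <- vnNeighbors(cell[1], cell[2], n)
    cnt[nb] <<- cnt[nb] + 1L
    new <- nb[!inReg[nb] & allowed[nb] & !onFront[nb], , drop = FALSE]
    if (nrow(new)) {
      onFront[new] <<- TRUE
      frontier <<- rbind(frontier, new)
    }
  }
  addCellEffects(start[1, ])
  k <- 1L
  while (k < area) {
    if (nrow(frontier) == 0) return(NULL)
    i <- sample.int(nrow(frontier), 1L, prob = 8^cnt[frontier])
    cell <- frontier[i, ]
    frontier <- frontier[-i, , drop = FALSE]
    onFront[cell[1], cell[2]] <- FALSE
    k <- k + 1L
    cells[k, ] <- cell
    inReg[cell[1], cell[2]] <- TRUE
    addCellEffects(cell)
  }
  unname(cells)
}

#' Generate an object-parsing stimulus
#'
#' Two disjoint, filled, 4-connected random regions on the grid, at least
#' one empty cell apart: region-grown polyominoes with compact interiors,
#' mixed with filled rectangles (probability `pRect`) so that homogeneous
#' regions of all widths — including ones wide enough for the coarsest
#' scales — occur.  A red cue sits inside one region; blue markers sit
#' inside both.
#'
#' @param gridSize grid side in cells (72 in the task of record).
#' @param rngSeed integer seed.
#' @param areaRange integer range of region areas in cells (both >= 2 so a
#'   cue and a marker fit); by default scaled to the grid so that two
#'   objects with sizable homogeneous interiors fit (60-1150 cells at
#'   gridSize 72).
#' @param pRect probability that a region is a filled rectangle instead of
#'   a region-grown blob.
#' @param maxTries placement retries.
#' @return a [Stimulus-class].
#' @export
generateObjectPair <- function(gridSize = 72L, rngSeed = NULL,
                               areaRange = NULL, pRect = 0.35,
                               maxTries = 200L) {
  n <- as.integer(gridSize)
  stopifnot(n >= 8L)
  if (is.null(areaRange))
    areaRange <- pmax(2L, c(round(n^2 / 86), round(n^2 / 4.5)))
  if (min(areaRange) < 2L)
    stop("objects must exceed one cell so a cue and a marker fit")
  oneRegion <- function(allowed) {
    if (runif(1) < pRect) {
      side <- max(2L, min(40L, n - 2L))
      for (tr in 1:30) {
        w <- sample(2:side, 1L); h <- sample(2:side, 1L)
        r0 <- sample.int(n - h + 1L, 1L); c0 <- sample.int(n - w + 1L, 1L)
        if (all(allowed[r0:(r0 + h - 1L), c0:(c0 + w - 1L)])) {
          m <- as.matrix(expand.grid(r0:(r0 + h - 1L), c0:(c0 + w - 1L)))
          dimnames(m) <- NULL
          return(m)
        }
      }
      return(NULL)
    }
    growRegion(n, sample(areaRange[1]:areaRange[2], 1L), allowed)
  }
  withSeed(rngSeed, {
    for (try in seq_len(maxTries)) {
      obj1 <- oneRegion(matrix(TRUE, n, n))
      if (is.null(obj1)) next
      obj2 <- oneRegion(!dilateCells(obj1, n))
      if (is.null(obj2)) next
      cueIdx <- sample.int(nrow(obj1), 1L)
      tgtIdx <- sample(setdiff(seq_len(nrow(obj1)), cueIdx), 1L)
      disIdx <- sample.int(nrow(obj2), 1L)
      return(newStimulus(n, "object", obj1, obj2,
                         fixationCell = obj1[cueIdx, ],
                         targetCell = obj1[tgtIdx, ],
                         distractorCell = obj2[disIdx, ],
                         seed = if (is.null(rngSeed)) NA_integer_ else rngSeed))
    }
    stop("failed to place two disjoint objects after ", maxTries, " attempts")
  })
}

# --- gate labels -------------------------------------------------------------

# Side of the padded canvas in cells for a stimulus processed at nScales.
paddedGridSize <- function(stim, nScales) {
  paddedSize(stim@gridSize * stim@cellPx, nScales) %/% stim@cellPx
}

# One straight, gap-free, 4-connected run: all cells on one row or column
# with consecutive positions (single cells count).
isStraightRun <- function(cells) {
  if (nrow(cells) == 1L) return(TRUE)
  r <- cells[, 1]; c <- cells[, 2]
  if (all(r == r[1])) {
    s <- sort(c)
    return(all(diff(s) == 1L))
  }
  if (all(c == c[1])) {
    s <- sort(r)
    return(all(diff(s) == 1L))
  }
  FALSE
}

# Block membership of cells: 1-based (block-row, block-col) for block side b.
cellBlocks <- function(cells, b) {
  cbind((cells[, 1] - 1L) %/% b + 1L, (cells[, 2] - 1L) %/% b + 1L)
}

# Per-block cell counts via an aggregation matrix (nb x G indicator).
blockCounts <- function(mask, b) {
  G <- nrow(mask); nb <- G %/% b
  A <- matrix(0, G, nb)
  A[cbind(seq_len(G), (seq_len(G) - 1L) %/% b + 1L)] <- 1
  crossprod(A, mask %*% A)
}

#' Gate labels for a curve-tracing stimulus
#'
#' For every scale and RF position: positive iff all curve cells inside the
#' RF belong to one curve and form a single straight (one row or one column),
#' gap-free, 4-connected run.  RFs containing cells of both curves, bends, or
#' nothing at all are negative.  Labels depend only on the generating
#' geometry, never on rendering.
#'
#' @param stim a curve-tracing [Stimulus-class].
#' @param nScales number of scales (default 4).
#' @return a [GateLabelSet-class]; map `l` has the resolution of hidden layer
#'   `l` on the zero-padded canvas.
#' @export
gateLabelsCurve <- function(stim, nScales = 4L) {
  if (stim@task != "curve") stop("stimulus is not a curve-tracing stimulus")
  G <- paddedGridSize(stim, nScales)
  labs <- lapply(seq_len(nScales), function(l) {
    b <- 3L^(l - 1L); nb <- G %/% b
    lab <- matrix(FALSE, nb, nb)
    bt <- cellBlocks(stim@target, b)
    bd <- cellBlocks(stim@distractor, b)
    idT <- bt[, 1] + nb * (bt[, 2] - 1L)
    idD <- bd[, 1] + nb * (bd[, 2] - 1L)
    shared <- intersect(idT, idD)
    check <- function(cells, ids) {
      for (id in setdiff(unique(ids), shared)) {
        sub <- cells[ids == id, , drop = FALSE]
        if (isStraightRun(sub)) lab[id] <<- TRUE
      }
    }
    check(stim@target, idT)
    check(stim@distractor, idD)
    lab
  })
  new("GateLabelSet", labels = labs, scales = as.integer(nScales),
      task = "curve")
}

#' Gate labels for an object-parsing stimulus
#'
#' Positive iff the RF is entirely covered by a single object (no background,
#' no second object); all-background RFs are negative.
#'
#' @inheritParams gateLabelsCurve
#' @param stim an object-parsing [Stimulus-class].
#' @return a [GateLabelSet-class].
#' @export
gateLabelsObject <- function(stim, nScales = 4L) {
  if (stim@task != "object") stop("stimulus is not an object-parsing stimulus")
  G <- paddedGridSize(stim, nScales)
  inT <- matrix(0, G, G); inT[stim@target] <- 1
  inD <- matrix(0, G, G); inD[stim@distractor] <- 1
  labs <- lapply(seq_len(nScales), function(l) {
    b <- 3L^(l - 1L)
    nt <- blockCounts(inT, b); nd <- blockCounts(inD, b)
    (nt == b * b & nd == 0) | (nd == b * b & nt == 0)
  })
  new("GateLabelSet", labels = labs, scales = as.integer(nScales),
      task = "object")
}

# --- geometry recovery and IO ------------------------------------------------

#' Recover cell-level geometry from a rendered image
#'
#' Classifies every cell block of the image as background, figure (green),
#' cue (red) or marker (blue); used to assert that rendering round-trips the
#' generating geometry.
#'
#' @param image H x W x 3 array.
#' @param cellPx pixels per cell (3).
#' @return list with logical matrices `figure`, plus `cue` and `markers`
#'   cell coordinate matrices.
#' @export
extractCells <- function(image, cellPx = 3L) {
  n <- nrow(image) %/% cellPx
  ctr <- seq(2, by = cellPx, length.out = n)  # center pixel of each block
  r <- image[ctr, ctr, 1]; g <- image[ctr, ctr, 2]; b <- image[ctr, ctr, 3]
  list(figure = g > 0 | r > 0 | b > 0,
       cue = which(r > 0 & g == 0, arr.ind = TRUE),
       markers = which(b > 0 & r == 0 & g == 0, arr.ind = TRUE))
}

#' Save a stimulus as PNG plus JSON sidecar
#'
#' @param stim a [Stimulus-class].
#' @param path file path without extension; writes `path.png` and
#'   `path.json`.
#' @return invisibly, the two file paths.
#' @export
saveStimulus <- function(stim, path) {
  pngPath <- paste0(path, ".png"); jsonPath <- paste0(path, ".json")
  png::writePNG(stim@image, pngPath)
  meta <- list(task = stim@task, gridSize = stim@gridSize,
               cellPx = stim@cellPx, seed = stim@seed,
               target = unname(stim@target), distractor = unname(stim@distractor),
               fixationCell = stim@fixationCell, targetCell = stim@targetCell,
               distractorCell = stim@distractorCell)
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(pngPath, jsonPath))
}

#' Load a stimulus saved by [saveStimulus()]
#'
#' @param path file path without extension.
#' @return a [Stimulus-class].
#' @export
readStimulus <- function(path) {
  img <- png::readPNG(paste0(path, ".png"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("Stimulus", image = img, gridSize = as.integer(meta$gridSize),
      cellPx = as.integer(meta$cellPx), task = meta$task,
      target = matrix(as.integer(meta$target), ncol = 2),
      distractor = matrix(as.integer(meta$distractor), ncol = 2),
      fixationCell = as.integer(meta$fixationCell),
      targetCell = as.integer(meta$targetCell),
      distractorCell = as.integer(meta$distractorCell),
      seed = as.integer(meta$seed))
}
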