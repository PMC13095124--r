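#' @include stimuli.R
NULL

#' Create (untrained) gate weights
#'
#' The scale-selection pathway: a shared 1x1 RGB projection `ff0`, and per
#' scale `l` a 20-feature-map convolution with kernel side `3^(l-1)` and
#' stride 1 followed by a single-output convolution with kernel side and
#' stride `3^l` whose sigmoid output feeds the -0.7 shift and rectification
#' of the gate.  Hidden kernels start near zero, so untrained gates are
#' silent everywhere (sigmoid(0) = 0.5 < 0.7).
#'
#' @param nScales number of scales (default 4).
#' @param seed integer RNG seed.
#' @return a [GateWeights-class].
#' @export
newGateWeights <- function(nScales = 4L, seed = NULL) {
  nScales <- as.integer(nScales)
  withSeed(seed, {
    scales <- lapply(seq_len(nScales), function(l) {
      k <- 3L^(l - 1L); K <- 3L^l
      list(wint = array(rnorm(k * k * 20, 0, sqrt(2 / (k * k))), c(k, k, 20)),
           bint = rep(0, 20),
           wout = array(rnorm(K * K * 20, 0, sqrt(2 / (20 * K * K))),
                        c(K, K, 20)),
           bout = 0)
    })
    new("GateWeights", ff0 = c(0.5, 0.5, 0.5), b0 = 0, scales = scales,
        nScales = nScales, task = "untrained")
  })
}

#' Run the scale-selection pathway
#'
#' @param stim a [Stimulus-class] or H x W x 3 image array (values in
#'   \[0, 1\]); padded to a multiple of `3^nScales` if necessary.
#' @param gw a [GateWeights-class].
#' @param wantIntermediate keep the intermediate 20-channel maps.
#' @return a [GateStack-class]; gate map `l` has resolution H/3^l and values
#'   in \[0, 0.3\].
#' @export
gateForward <- function(stim, gw, wantIntermediate = FALSE) {
  img <- padImage(asImage(stim), gw@nScales)
  res <- .cpp_gate_forward(img, list(ff0 = gw@ff0, b0 = gw@b0,
                                     scales = gw@scales), wantIntermediate)
  new("GateStack", x0 = res$x0, xint = if (wantIntermediate) res$xint else list(),
      sig = res$sig, xgate = res$xgate)
}

# --- supervised gate training ------------------------------------------------

# Per-scale patch geometry: kernel side k, block side K (pixels), margin m.
gateGeom <- function(l) {
  k <- 3L^(l - 1L)
  list(k = k, K = 3L^l, m = (k - 1L) %/% 2L)
}

# Extract the (side x side x 3) patch around block (bi, bj) at scale l from a
# padded image, zero-filled outside the canvas.
gatePatch <- function(img, l, bi, bj) {
  g <- gateGeom(l)
  side <- g$K + 2L * g$m
  out <- array(0, c(side, side, 3))
  r0 <- (bi - 1L) * g$K + 1L - g$m
  c0 <- (bj - 1L) * g$K + 1L - g$m
  rr <- max(1L, r0):min(nrow(img), r0 + side - 1L)
  cc <- max(1L, c0):min(ncol(img), c0 + side - 1L)
  out[rr - r0 + 1L, cc - c0 + 1L, ] <- img[rr, cc, , drop = FALSE]
  out
}

# Forward/backward for one patch at one scale (compiled; exploits the
# sparsity of the stimulus).  Returns loss, prediction and gradients.
gatePatchPass <- function(patch, y, wgt, ff0, b0, sc, l, backward = TRUE) {
  .cpp_gate_patch_pass(patch, y, wgt, ff0, b0, sc$wint, sc$bint, sc$wout,
                       sc$bout, 3L^l, backward)
}

adamInit <- function(x) list(m = x * 0, v = x * 0, t = 0)
adamStep <- function(x, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^st$t); vh <- st$v / (1 - b2^st$t)
  list(x = x - lr * mh / (sqrt(vh) + eps), st = st)
}

# Sample up to nPos positive and nNeg negative blocks for one scale; a
# fraction hardFrac of the negatives comes from occupied-but-ambiguous
# blocks (the decision-relevant ones), the rest from empty background.
sampleBlocks <- function(lab, occ, nPos, nNeg, hardFrac = 0.5) {
  pos <- which(lab, arr.ind = TRUE)
  hard <- which(occ & !lab, arr.ind = TRUE)
  easy <- which(!lab & !occ, arr.ind = TRUE)
  pick <- function(m, n, y) {
    if (nrow(m) == 0 || n <= 0) return(NULL)
    cbind(m[sample.int(nrow(m), min(n, nrow(m))), , drop = FALSE], y = y)
  }
  nh <- ceiling(nNeg * hardFrac)
  rbind(pick(pos, nPos, 1), pick(hard, nh, 0),
        pick(easy, nNeg - min(nh, nrow(hard)), 0))
}

#' Train the scale-selection pathway
#'
#' Supervised training against geometry-derived labels
#' ([gateLabelsCurve()] / [gateLabelsObject()]): a cross-entropy loss on the
#' sigmoid output is computed independently at each scale; scale-specific
#' kernels receive gradients only from their own scale's loss while the
#' shared projection `ff0` accumulates gradients from all scales (Adam,
#' learning rate `lr`).  Class imbalance is handled by stratified sampling
#' of RF positions: per stimulus and scale, up to `perStim` positive blocks
#' and as many negatives (half of them occupied-but-ambiguous "hard"
#' negatives) enter the loss.
#'
#' @param task `"curve"` or `"object"`.
#' @param nStimuli training stimuli (50,000 / 10,000 in the experiment of
#'   record; smaller values give desk-scale runs).
#' @param epochs passes over the stimulus set (80 in the experiment of
#'   record).
#' @param lr Adam learning rate (1e-3).
#' @param perStim sampled positive RF positions per stimulus and scale
#'   (recycled to one value per scale; coarse scales cost more per sample).
#' @param scaleEvery per-scale visit period: scale `l` is trained on every
#'   `scaleEvery[l]`-th stimulus (the largest scale is by far the most
#'   expensive per sample).
#' @param batchStims stimuli per Adam step (gradients are averaged).
#' @param gridSize stimulus grid side; defaults to 36 (curve) / 72 (object).
#' @param lengths curve lengths sampled during gate training (curve task).
#' @param nScales number of scales.
#' @param seed integer RNG seed.
#' @param verbose print running loss.
#' @return a trained [GateWeights-class].
#' @export
trainGates <- function(task = c("curve", "object"), nStimuli = NULL,
                       epochs = 80L, lr = 1e-3, perStim = c(4L, 4L, 3L, 1L),
                       scaleEvery = c(1L, 1L, 1L, 2L), batchStims = 4L,
                       gridSize = NULL, lengths = 3:12, nScales = 4L,
                       seed = NULL, verbose = FALSE) {
  task <- match.arg(task)
  if (is.null(nStimuli)) nStimuli <- if (task == "curve") 50000L else 10000L
  if (is.null(gridSize)) gridSize <- if (task == "curve") 36L else 72L
  perStim <- rep_len(as.integer(perStim), nScales)
  scaleEvery <- rep_len(as.integer(scaleEvery), nScales)
  withSeed(seed, {
    gw <- newGateWeights(nScales)
    # pregenerate geometry + labels
    stims <- vector("list", nStimuli)
    labs <- vector("list", nStimuli)
    for (i in seq_len(nStimuli)) {
      s <- if (task == "curve")
        generateCurvePair(gridSize, sample(lengths, 1L))
      else generateObjectPair(gridSize)
      stims[[i]] <- s
      labs[[i]] <- if (task == "curve") gateLabelsCurve(s, nScales)
                   else gateLabelsObject(s, nScales)
    }
    # occupied blocks per scale (figure cells present)
    occs <- lapply(seq_len(nStimuli), function(i) {
      s <- stims[[i]]
      G <- paddedGridSize(s, nScales)
      m <- matrix(FALSE, G, G)
      m[rbind(s@target, s@distractor)] <- TRUE
      lapply(seq_len(nScales), function(l) {
        b <- 3L^(l - 1L); nb <- G %/% b
        out <- matrix(FALSE, nb, nb)
        cells <- which(m, arr.ind = TRUE)
        out[cbind((cells[, 1] - 1L) %/% b + 1L, (cells[, 2] - 1L) %/% b + 1L)] <- TRUE
        out
      })
    })
    ad <- list(ff0 = adamInit(gw@ff0), b0 = adamInit(gw@b0))
    for (l in seq_len(nScales)) {
      sc <- gw@scales[[l]]
      ad[[paste0("s", l)]] <- list(wint = adamInit(sc$wint),
                                   bint = adamInit(sc$bint),
                                   wout = adamInit(sc$wout),
                                   bout = adamInit(sc$bout))
    }
    zeroAcc <- function() {
      a <- lapply(seq_len(nScales), function(l) {
        sc <- gw@scales[[l]]
        list(gwint = sc$wint * 0, gbint = sc$bint * 0, gwout = sc$wout * 0,
             gbout = 0, n = 0)
      })
      list(scales = a, gff0 = c(0, 0, 0), gb0 = 0, n0 = 0)
    }
    acc <- zeroAcc()
    runLoss <- rep(0, nScales); nLoss <- rep(0, nScales)
    visit <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nStimuli)
      for (i in ord) {
        visit <- visit + 1L
        s <- stims[[i]]
        img <- padImage(s@image, nScales)
        effLr <- if (ep > 0.6 * epochs) lr * 0.3 else lr
        for (l in seq_len(nScales)) {
          if (visit %% scaleEvery[l] != 0L) next
          # coarse scales see twice as many negatives, all of them hard:
          # precision there decides whether enhancement can spill
          blocks <- sampleBlocks(labs[[i]]@labels[[l]], occs[[i]][[l]],
                                 perStim[l],
                                 perStim[l] * (1L + (l >= 2L)),
                                 hardFrac = if (l >= 2L) 1 else 0.5)
          if (is.null(blocks) || nrow(blocks) == 0) next
          sc <- gw@scales[[l]]
          for (r in seq_len(nrow(blocks))) {
            p <- gatePatch(img, l, blocks[r, 1], blocks[r, 2])
            res <- gatePatchPass(p, blocks[r, 3], 1, gw@ff0, gw@b0, sc, l)
            runLoss[l] <- runLoss[l] + res$loss; nLoss[l] <- nLoss[l] + 1
            al <- acc$scales[[l]]
            al$gwint <- al$gwint + res$gwint; al$gbint <- al$gbint + res$gbint
            al$gwout <- al$gwout + res$gwout; al$gbout <- al$gbout + res$gbout
            al$n <- al$n + 1
            acc$scales[[l]] <- al
            acc$gff0 <- acc$gff0 + res$gff0; acc$gb0 <- acc$gb0 + res$gb0
            acc$n0 <- acc$n0 + 1
          }
        }
        if (visit %% batchStims == 0L) {
          for (l in seq_len(nScales)) {
            al <- acc$scales[[l]]
            if (al$n == 0) next
            sc <- gw@scales[[l]]
            ast <- ad[[paste0("s", l)]]
            up <- adamStep(sc$wint, al$gwint / al$n, ast$wint, effLr)
            sc$wint <- up$x; ast$wint <- up$st
            up <- adamStep(sc$bint, al$gbint / al$n, ast$bint, effLr)
            sc$bint <- up$x; ast$bint <- up$st
            up <- adamStep(sc$wout, al$gwout / al$n, ast$wout, effLr)
            sc$wout <- up$x; ast$wout <- up$st
            up <- adamStep(sc$bout, al$gbout / al$n, ast$bout, effLr)
            sc$bout <- up$x; ast$bout <- up$st
            ad[[paste0("s", l)]] <- ast
            gw@scales[[l]] <- sc
          }
          if (acc$n0 > 0) {
            up <- adamStep(gw@ff0, acc$gff0 / acc$n0, ad$ff0, effLr)
            gw@ff0 <- up$x; ad$ff0 <- up$st
            up <- adamStep(gw@b0, acc$gb0 / acc$n0, ad$b0, effLr)
            gw@b0 <- up$x; ad$b0 <- up$st
          }
          acc <- zeroAcc()
        }
      }
      if (verbose) {
        message(sprintf("epoch %d: per-scale loss %s", ep,
                        paste(sprintf("%.3f", runLoss / pmax(nLoss, 1)),
                              collapse = " ")))
        runLoss[] <- 0; nLoss[] <- 0
      }
    }
    gw@task <- task
    gw
  })
}

#' Gate accuracy on held-out stimuli
#'
#' Fraction of RF positions, per scale, where the thresholded sigmoid output
#' (active iff > 0.7, i.e. gate > 0) matches the geometry-derived label.
#'
#' @param gw a trained [GateWeights-class].
#' @param stimuli list of [Stimulus-class] objects.
#' @param task label rule to evaluate against (defaults to `gw@task`).
#' @return numeric vector of per-scale accuracies.
#' @export
gateAccuracy <- function(gw, stimuli, task = gw@task) {
  acc <- matrix(0, length(stimuli), gw@nScales)
  for (i in seq_along(stimuli)) {
    s <- stimuli[[i]]
    lab <- if (task == "curve") gateLabelsCurve(s, gw@nScales)
           else gateLabelsObject(s, gw@nScales)
    gs <- gateForward(s, gw)
    for (l in seq_len(gw@nScales))
      acc[i, l] <- mean((gs@sig[[l]] > 0.7) == lab@labels[[l]])
  }
  colMeans(acc)
}

#' Scale usage and arrival time along the target figure
#'
#' For every target cell: the coarsest scale whose gate is active over that
#' cell, and the timestep at which the pyramidal enhancement of the covering
#' unit at that scale reached 90% of its maximum (requires a state recorded
#' with `record = TRUE`).
#'
#' @param state a [NetworkState-class] with history.
#' @param gates the trial's [GateStack-class].
#' @param stim the trial's [Stimulus-class].
#' @return data.frame with columns `row`, `col`, `scale`, `latency`.
#' @export
scaleUsageMap <- function(state, gates, stim) {
  if (length(state@history) == 0)
    stop("state must be recorded with record = TRUE")
  cells <- stim@target
  out <- data.frame(row = cells[, 1], col = cells[, 2], scale = NA_integer_,
                    latency = NA_integer_)
  nS <- length(gates@xgate)
  for (i in seq_len(nrow(cells))) {
    px <- (cells[i, ] - 1L) * stim@cellPx + 1L  # top-left pixel of the cell
    sc <- NA_integer_
    for (l in rev(seq_len(nS))) {
      u <- (px - 1L) %/% 3L^l + 1L
      if (gates@xgate[[l]][u[1], u[2]] > 0) { sc <- l; break }
    }
    out$scale[i] <- sc
    if (!is.na(sc)) {
      u <- (px - 1L) %/% 3L^sc + 1L
      series <- vapply(state@history, function(h) {
        y <- h[[sc + 1L]]
        max(y[u[1], u[2], ])
      }, numeric(1))
      out$latency[i] <- modulationLatency(series, flagZero = TRUE)
    }
  }
  out
}
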