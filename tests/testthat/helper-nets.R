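# Shared fixtures: hand-built networks, loop-based convolution oracles, and
# a session cache for expensive trained objects.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# Single-scale network that propagates enhancement exactly one cell per step:
# the red cue's feedforward drive (2) beats the SOM floor (1); green/blue
# drive (0.6) needs VIP disinhibition, which saturating horizontal weights
# (2) provide from any active neighbor.
chainWeights <- function() {
  w <- newRecurrentWeights(1L, zero = TRUE)
  k <- w@kernels
  k$li0[2, 2, 1, 1] <- -1; k$li0[2, 2, 2, 2] <- -1; k$li0[2, 2, 3, 3] <- -1
  k$ff2[[1]][, , 1, 1] <- 2 / 9    # red
  k$ff2[[1]][, , 2, 1] <- 0.6 / 9  # green
  k$ff2[[1]][, , 3, 1] <- 0.6 / 9  # blue
  h <- k$hor[[1]]
  h[horizontalMask(1, 1)] <- 2
  k$hor[[1]] <- h
  k$wskip[[2]][] <- 1
  initialize(w, kernels = k)
}

# Gate stack with the scale-1 gate fully open over a set of grid cells.
cellGate <- function(cells, gridSize, nScales = 1L, cellPx = 3L) {
  G <- as.integer(ceiling(gridSize * cellPx / 3^nScales) * 3^nScales) %/% cellPx
  lapply(seq_len(nScales), function(l) {
    b <- 3L^(l - 1L); nb <- (G * cellPx) %/% 3L^l
    g <- matrix(0, nb, nb)
    if (l == 1L) g[cells] <- 0.3
    g
  })
}

# A straight horizontal curve stimulus built by hand (no distractor overlap).
straightCurveStimulus <- function(len = 7L, gridSize = 12L, row = 4L,
                                  col0 = 2L) {
  target <- cbind(row, col0:(col0 + len - 1L))
  distractor <- cbind(row + 5L, col0:(col0 + len - 1L))
  tracenet:::newStimulus(gridSize, "curve", target, distractor,
                         fixationCell = target[1, ],
                         targetCell = target[len, ],
                         distractorCell = distractor[len, ], seed = 0L)
}

# Loop-based oracle for the gate forward pass (naive direct evaluation).
oracleGateForward <- function(image, gw) {
  H <- dim(image)[1]; W <- dim(image)[2]
  x0 <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    x0[i, j] <- max(0, sum(gw@ff0 * image[i, j, ]) + gw@b0)
  out <- list()
  for (l in seq_len(gw@nScales)) {
    sc <- gw@scales[[l]]
    k <- dim(sc$wint)[1]; K <- 3L^l; half <- (k - 1L) %/% 2L
    nf <- dim(sc$wint)[3]
    xint <- array(0, c(H, W, nf))
    for (f in seq_len(nf)) for (i in seq_len(H)) for (j in seq_len(W)) {
      s <- 0
      for (u in seq_len(k)) for (v in seq_len(k)) {
        ii <- i + u - 1L - half; jj <- j + v - 1L - half
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
          s <- s + sc$wint[u, v, f] * x0[ii, jj]
      }
      xint[i, j, f] <- max(0, s + sc$bint[f])
    }
    h <- H %/% K; w <- W %/% K
    gate <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      s <- sc$bout
      for (f in seq_len(nf)) for (u in seq_len(K)) for (v in seq_len(K))
        s <- s + sc$wout[u, v, f] * xint[(i - 1) * K + u, (j - 1) * K + v, f]
      gate[i, j] <- max(0, 1 / (1 + exp(-s)) - 0.7)
    }
    out[[l]] <- gate
  }
  out
}

# Loop-based oracle for the Q readout (Eq.-by-Eq. transposed convolution).
oracleQMap <- function(Y, kernels) {
  H <- dim(Y[[1]])[1]; W <- dim(Y[[1]])[2]
  q <- matrix(0, H, W)
  for (c in seq_len(dim(Y[[1]])[3]))
    q <- q + kernels$wskip[[1]][1, 1, c] * Y[[1]][, , c]
  for (l in seq_along(Y)[-1]) {
    K <- 3L^(l - 1L)
    Yl <- Y[[l]]; wl <- kernels$wskip[[l]]
    for (c in seq_len(dim(Yl)[3]))
      for (i in seq_len(dim(Yl)[1])) for (j in seq_len(dim(Yl)[2]))
        for (u in seq_len(K)) for (v in seq_len(K))
          q[(i - 1) * K + u, (j - 1) * K + v] <-
            q[(i - 1) * K + u, (j - 1) * K + v] + wl[u, v, c] * Yl[i, j, c]
  }
  q
}

# Random gate stack at the layer resolutions of an H x H input.
randomGates <- function(H, nScales, density = 0.7) {
  lapply(seq_len(nScales), function(l) {
    r <- H / 3^l
    matrix(runif(r * r, 0, 0.3) * (runif(r * r) < density), r, r)
  })
}

# Loop-based stride-3 convolution oracle (the feedforward drive of layer l).
oracleConv3s3 <- function(yin, ker) {
  h <- dim(yin)[1] %/% 3L; w <- dim(yin)[2] %/% 3L
  ci <- dim(ker)[3]; co <- dim(ker)[4]
  out <- array(0, c(h, w, co))
  for (cc in seq_len(co)) for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (ic in seq_len(ci)) for (u in 1:3) for (v in 1:3)
      s <- s + ker[u, v, ic, cc] * yin[(i - 1) * 3 + u, (j - 1) * 3 + v, ic]
    out[i, j, cc] <- s
  }
  out
}
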