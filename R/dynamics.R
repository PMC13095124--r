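#' @include utils.R
NULL

# Channel counts per layer: RGB input, 1 channel in layer 1, 6 above.
layerChannels <- function(nScales) {
  c(3L, 1L, rep(6L, max(0L, nScales - 1L)))[seq_len(nScales + 1L)]
}

#' Create a recurrent weight set
#'
#' Kernel families (all learnable):
#' \describe{
#'   \item{ff2}{feedforward kernels of the recurrent pathway, 3x3, stride 3,
#'     one per layer; initialized non-negative (excitatory drive).}
#'   \item{fb}{feedback kernels, transposed 3x3, stride 3, so a unit receives
#'     feedback only from the unit above with an overlapping RF.}
#'   \item{hor}{horizontal kernels, masked to the von Neumann neighborhood
#'     (the four nearest neighbors); drive VIP interneurons.}
#'   \item{li0}{input-layer lateral inhibition, a single nonzero (center)
#'     position per 3x3 kernel mixing channels at one pixel; initialized
#'     inhibitory (negative diagonal) so `-li0 (x) SOM` releases the sensory
#'     drive into the input-layer blackboard.}
#'   \item{wskip}{readout skip kernels: 1x1 for the input layer, and for layer
#'     l a transposed kernel projecting each unit to its 3^l x 3^l output
#'     footprint.}
#' }
#'
#' Initialization keeps early pyramidal activity above the SOM floor (ff2
#' drive near 1) so that credit can flow through every kernel family from the
#' first trials; readout kernels start near zero.
#'
#' @param nScales number of hidden layers (1 to 4; the model of record uses 4).
#' @param seed integer RNG seed.
#' @param zero logical; if `TRUE` all kernels are zero (useful for building
#'   networks by hand in tests).
#' @return a [RecurrentWeights-class].
#' @export
newRecurrentWeights <- function(nScales = 4L, seed = NULL, zero = FALSE) {
  nScales <- as.integer(nScales)
  stopifnot(nScales >= 1L, nScales <= 4L)
  C <- layerChannels(nScales)
  withSeed(seed, {
    rand <- function(dims, lo, hi) {
      if (zero) array(0, dims) else array(runif(prod(dims), lo, hi), dims)
    }
    # per-layer scale of the feedforward drive: every layer starts near its
    # SOM floor of 1 for the typical activity of the layer below (layer 1
    # sees ~9 near-unit input pixels per RF, layer 2 a few tenths-strong
    # single-channel cells, layers 3-4 a 6-channel version of the same), so
    # no population sits dead on the ReLU floor where the accessory network
    # could never assign it credit
    ff2Hi <- c(0.25, 0.25, 0.25, 0.25)[seq_len(nScales)]
    ff2 <- lapply(seq_len(nScales), function(l)
      rand(c(3, 3, C[l], C[l + 1]), 0, ff2Hi[l]))
    # feedback into the input layer starts silent: its early effect is to
    # suppress the attended curve's sensory relay (the release term shrinks
    # as VIP0 rises), which seeds a stable anti-discrimination; it is grown
    # by learning only where it helps
    fb <- lapply(seq_len(nScales), function(l)
      rand(c(3, 3, C[l + 1], C[l]), 0, if (l == 1) 0 else 0.10))
    # horizontal kernels start strong enough that accessory credit from a
    # chosen marker reaches the cue's feedforward route within a few
    # backward steps; with weak chains the credit product decays and the
    # figure's layer-1 activity can die before discrimination is learned
    hor <- lapply(seq_len(nScales), function(l) {
      h <- rand(c(3, 3, C[l + 1], C[l + 1]), 0, 0.5)
      h[!horizontalMask(C[l + 1], C[l + 1])] <- 0
      h
    })
    li0 <- array(0, c(3, 3, C[1], C[1]))
    if (!zero) {
      ctr <- -diag(C[1]) + matrix(runif(C[1]^2, -0.02, 0.02), C[1])
      li0[2, 2, , ] <- ctr
    }
    # readout: input-layer and layer-1 skips start nonzero (they bootstrap
    # action selection onto figure pixels and carry the earliest
    # discrimination signal); skips from coarser layers start at zero so
    # spontaneously active coarse units do not add noise to the early Q map
    # (zero-valued skips still receive their full gradient)
    wskip <- c(list(rand(c(1, 1, C[1]), -0.05, 0.05)),
               lapply(seq_len(nScales), function(l)
                 rand(c(3^l, 3^l, C[l + 1]), -0.05, 0.05)))
    new("RecurrentWeights", nScales = nScales, channels = C,
        kernels = list(ff2 = ff2, fb = fb, hor = hor, li0 = li0,
                       wskip = wskip))
  })
}

# Precompute the phi-gated inputs the engine consumes: phi(X) on the padded
# image and phi(gate) per scale.
prepareInputs <- function(image, gates, nScales, bump = FALSE) {
  xg <- if (is(gates, "GateStack")) gates@xgate else gates
  stopifnot(length(xg) >= nScales)
  # the gate stack defines the padded canvas (gate maps may come from a
  # deeper stack, padded to a larger multiple than this network needs)
  want <- nrow(xg[[1]]) * 3L
  img <- padImage(image, nScales)
  if (nrow(img) < want) {
    out <- array(0, c(want, want, dim(img)[3]))
    out[seq_len(nrow(img)), seq_len(ncol(img)), ] <- img
    img <- out
  }
  phiX <- phiGate(img, bump)
  phiG <- lapply(xg[seq_len(nScales)], phiGate, bump = bump)
  list(phiX = phiX, phiG = phiG)
}

asImage <- function(x) {
  if (is(x, "Stimulus")) x@image else x
}

#' Iterate the recurrent network to a fixed point
#'
#' Runs the disinhibitory dynamics from an all-zero state: VIP interneurons
#' integrate horizontal and feedback drive from the previous step, SOM
#' activity is `ReLU(1 - VIP)` (tonically active, silenced by VIP), and
#' pyramidal layers sweep bottom-up within the step, each bounded by its
#' phi-gated feedforward drive minus SOM inhibition.  Iteration stops when
#' the largest absolute change of any population is at most `tol`, or after
#' `tMax` steps.
#'
#' @param stim a [Stimulus-class] or an H x W x 3 image array.
#' @param gates a [GateStack-class] from [gateForward()] (or a list of gate
#'   matrices at the layer resolutions).
#' @param weights a [RecurrentWeights-class].
#' @param tMax maximum number of timesteps (default 30).
#' @param tol convergence tolerance on the activity change (default 1e-6).
#' @param record keep the per-timestep pyramidal history (needed for latency
#'   analyses).
#' @param bump use the non-monotone gate nonlinearity (see [phiGate()]).
#' @return a [NetworkState-class].
#' @export
runToFixedPoint <- function(stim, gates, weights, tMax = 30L, tol = 1e-6,
                            record = FALSE, bump = FALSE) {
  stopifnot(tMax >= 1L)
  inp <- prepareInputs(asImage(stim), gates, weights@nScales, bump)
  res <- .cpp_forward(inp$phiX, inp$phiG, weights@kernels, as.integer(tMax),
                      tol, record)
  new("NetworkState", Y = res$Y, VIP = res$VIP, SOM = res$SOM,
      VIPpre = res$VIPpre, T = as.integer(res$T),
      converged = isTRUE(res$converged),
      history = if (record) res$history else list())
}

#' Apply one synchronous network update
#'
#' A single step of the dynamics from a given state; mainly for inspecting
#' the step map and asserting its invariants (boundedness, gating hard-off).
#'
#' @inheritParams runToFixedPoint
#' @param state a [NetworkState-class] holding the activity at `t - 1`.
#' @return a [NetworkState-class] at time `t` (history is not carried).
#' @export
stepNetwork <- function(state, stim, gates, weights, bump = FALSE) {
  inp <- prepareInputs(asImage(stim), gates, weights@nScales, bump)
  res <- .cpp_step(inp$phiX, inp$phiG, weights@kernels, state@Y, state@VIP,
                   state@SOM)
  new("NetworkState", Y = res$Y, VIP = res$VIP, SOM = res$SOM,
      VIPpre = res$VIPpre, T = state@T + 1L, converged = FALSE,
      history = list())
}

#' All-zero network state matching a stimulus and weight set
#'
#' @inheritParams runToFixedPoint
#' @return a [NetworkState-class] at `t = 0`.
#' @export
zeroState <- function(stim, weights) {
  img <- padImage(asImage(stim), weights@nScales)
  H <- dim(img)[1]; W <- dim(img)[2]
  C <- weights@channels
  Y <- lapply(0:weights@nScales, function(l)
    array(0, c(H / 3^l, W / 3^l, C[l + 1])))
  som <- lapply(Y, function(y) y + 1)  # tonic SOM baseline
  new("NetworkState", Y = Y, VIP = Y, SOM = som, VIPpre = Y, T = 0L,
      converged = FALSE, history = list())
}
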