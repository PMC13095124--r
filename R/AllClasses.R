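#' @include tracenet-package.R
NULL

#' Rendered stimulus with exact ground truth
#'
#' A raster stimulus (RGB values in \[0, 1\]) on an `gridSize` x `gridSize`
#' cell grid, each cell rendered as a `cellPx` x `cellPx` pixel block.  Figure
#' cells are green, the fixation cue cell red, and the two candidate
#' eye-movement targets blue (one per figure).  `target` and `distractor` hold
#' the generating geometry: for curve stimuli an ordered matrix of (row, col)
#' cells along the curve, for object stimuli the cells of the filled region.
#'
#' @slot image numeric array, height x width x 3 (R, G, B), values in \[0, 1\].
#' @slot gridSize integer, cells per side.
#' @slot cellPx integer, pixels per cell side (3).
#' @slot task `"curve"` or `"object"`.
#' @slot target,distractor integer matrices (n x 2) of 1-based (row, col) cells.
#' @slot fixationCell,targetCell,distractorCell length-2 integer (row, col).
#' @slot seed integer seed used by the generator.
#' @exportClass Stimulus
setClass("Stimulus", representation(
  image = "array", gridSize = "integer", cellPx = "integer",
  task = "character", target = "matrix", distractor = "matrix",
  fixationCell = "integer", targetCell = "integer",
  distractorCell = "integer", seed = "integer"))

setValidity("Stimulus", function(object) {
  msg <- character()
  n <- object@gridSize * object@cellPx
  if (!all(dim(object@image) == c(n, n, 3)))
    msg <- c(msg, "image dimensions must equal gridSize * cellPx x 3 channels")
  if (any(object@image < 0) || any(object@image > 1))
    msg <- c(msg, "image values must lie in [0, 1]")
  key <- function(m) paste(m[, 1], m[, 2])
  if (length(intersect(key(object@target), key(object@distractor))))
    msg <- c(msg, "target and distractor must not share a cell")
  red <- sum(object@image[, , 1] > 0 & object@image[, , 2] == 0)
  if (red != object@cellPx^2) msg <- c(msg, "exactly one red cue cell required")
  blue <- sum(object@image[, , 3] > 0 & object@image[, , 2] == 0 &
                object@image[, , 1] == 0)
  if (blue != 2 * object@cellPx^2)
    msg <- c(msg, "exactly two blue marker cells required")
  if (length(msg)) msg else TRUE
})

#' Per-scale gate labels for supervised training
#'
#' Binary maps, one per scale, marking receptive fields whose content is
#' unambiguous: for curves, all cells inside the RF belong to one curve and
#' form a single straight, 4-connected run; for objects, the RF is entirely
#' covered by a single object.  Map `l` has the resolution of hidden layer `l`
#' on the zero-padded canvas.
#'
#' @slot labels list of logical matrices, one per scale.
#' @slot scales integer, number of scales.
#' @slot task `"curve"` or `"object"`.
#' @exportClass GateLabelSet
setClass("GateLabelSet", representation(
  labels = "list", scales = "integer", task = "character"))

#' Weights of the feedforward scale-selection pathway
#'
#' A shared 1x1 input projection followed, per scale, by a 20-feature-map
#' stride-1 convolution (kernel side 3^(l-1)) and a single-output convolution
#' with kernel side and stride 3^l whose sigmoid output, shifted by -0.7 and
#' rectified, is the gate passed to the recurrent pathway.
#'
#' @slot ff0 numeric length-3 (R, G, B weights of the shared projection).
#' @slot b0 numeric scalar bias of the shared projection.
#' @slot scales list, one entry per scale with elements `wint` (k x k x 20),
#'   `bint` (length 20), `wout` (K x K x 20), `bout` (scalar).
#' @slot nScales integer.
#' @slot task character, task the gates were trained for (or `"untrained"`).
#' @exportClass GateWeights
setClass("GateWeights", representation(
  ff0 = "numeric", b0 = "numeric", scales = "list", nScales = "integer",
  task = "character"))

#' Activity of the feedforward scale-selection pathway
#'
#' @slot x0 matrix, shared input projection (H x W).
#' @slot xint list of H x W x 20 arrays (may be empty if not requested).
#' @slot sig list of per-scale sigmoid outputs (before the -0.7 shift).
#' @slot xgate list of per-scale gate maps, resolution H/3^l, values in
#'   \[0, 0.3\].
#' @exportClass GateStack
setClass("GateStack", representation(
  x0 = "matrix", xint = "list", sig = "list", xgate = "list"))

setValidity("GateStack", function(object) {
  for (g in object@xgate) {
    if (any(g < 0) || any(g > 0.3 + 1e-12))
      return("gate values must lie in [0, 0.3]")
  }
  TRUE
})

#' Learnable kernels of the recurrent pathway
#'
#' @slot nScales integer, number of hidden layers (scales).
#' @slot channels integer vector, channels per layer (input layer first).
#' @slot kernels list with elements `ff2`, `fb`, `hor`, `li0`, `wskip`; see
#'   [newRecurrentWeights()] for shapes and constraints.
#' @exportClass RecurrentWeights
setClass("RecurrentWeights", representation(
  nScales = "integer", channels = "integer", kernels = "list"))

setValidity("RecurrentWeights", function(object) {
  k <- object@kernels
  msg <- character()
  mask <- horizontalMask()
  for (h in k$hor)
    if (any(h[!mask] != 0))
      msg <- c(msg, "horizontal kernels must be zero outside the von Neumann neighborhood")
  li <- k$li0
  center <- array(FALSE, dim(li)); center[2, 2, , ] <- TRUE
  if (any(li[!center] != 0))
    msg <- c(msg, "input-layer lateral kernel must be zero off-center")
  if (!all(vapply(k, function(x) all(is.finite(unlist(x))), logical(1))))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Time-evolved state of the recurrent network
#'
#' @slot Y,VIP,SOM lists of arrays (input layer first): pyramidal, VIP and
#'   SOM population activity at the final timestep.
#' @slot VIPpre list of pre-clip VIP drives (needed by the accessory pass).
#' @slot T integer, timestep at which the state was read out.
#' @slot converged logical, whether a fixed point was reached before `tMax`.
#' @slot history list (one entry per timestep) of pyramidal activity lists,
#'   present only when recording was requested.
#' @exportClass NetworkState
setClass("NetworkState", representation(
  Y = "list", VIP = "list", SOM = "list", VIPpre = "list",
  T = "integer", converged = "logical", history = "list"))

#' One reinforcement-learning trial
#'
#' @slot action length-2 integer, chosen output pixel (row, col).
#' @slot qa numeric, Q-value of the chosen pixel.
#' @slot reward numeric, 0 or 1.
#' @slot delta numeric, reward prediction error reward - qa.
#' @slot T integer, convergence timestep of the forward phase.
#' @slot greedy logical, whether the action was the greedy one.
#' @exportClass TrialRecord
setClass("TrialRecord", representation(
  action = "integer", qa = "numeric", reward = "numeric", delta = "numeric",
  T = "integer", greedy = "logical"))

#' Regression fit of human on model reaction times
#'
#' @slot n integer, observations used (after outlier removal).
#' @slot k integer, number of predictors.
#' @slot r2 numeric, coefficient of determination.
#' @slot se numeric, standard error of R^2.
#' @slot coef numeric, intercept and slope of the OLS fit.
#' @exportClass RTFit
setClass("RTFit", representation(
  n = "integer", k = "integer", r2 = "numeric", se = "numeric",
  coef = "numeric"))

setValidity("RTFit", function(object) {
  if (object@r2 < 0 || object@r2 > 1) return("r2 must lie in [0, 1]")
  if (object@n <= object@k + 1) return("need n > k + 1 observations")
  TRUE
})

# --- show methods ------------------------------------------------------------

setMethod("show", "Stimulus", function(object) {
  cat(sprintf("Stimulus (%s task): %dx%d grid, %dx%d px\n", object@task,
              object@gridSize, object@gridSize, nrow(object@image),
              ncol(object@image)))
  cat(sprintf("  cue (%d,%d) -> target (%d,%d); distractor marker (%d,%d)\n",
              object@fixationCell[1], object@fixationCell[2],
              object@targetCell[1], object@targetCell[2],
              object@distractorCell[1], object@distractorCell[2]))
  cat(sprintf("  figure sizes: %d / %d cells\n", nrow(object@target),
              nrow(object@distractor)))
})

setMethod("show", "GateWeights", function(object) {
  cat(sprintf("GateWeights: %d scales, task '%s'\n", object@nScales,
              object@task))
})

setMethod("show", "GateStack", function(object) {
  act <- vapply(object@xgate, function(g) mean(g > 0), numeric(1))
  cat(sprintf("GateStack: %d scales; active gate fraction per scale: %s\n",
              length(object@xgate), paste(sprintf("%.3f", act), collapse = " ")))
})

setMethod("show", "RecurrentWeights", function(object) {
  np <- sum(vapply(object@kernels, function(k) length(unlist(k)), numeric(1)))
  cat(sprintf("RecurrentWeights: %d scales, channels (%s), %d parameters\n",
              object@nScales, paste(object@channels, collapse = ","), np))
})

setMethod("show", "NetworkState", function(object) {
  cat(sprintf("NetworkState: %d layers, T = %d, %s\n", length(object@Y) - 1L,
              object@T,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "RTFit", function(object) {
  cat(sprintf("RTFit: R^2 = %.3f (SE %.3f), n = %d, k = %d\n", object@r2,
              object@se, object@n, object@k))
})

# --- accessors ---------------------------------------------------------------

#' @describeIn Stimulus-class the rendered image array.
#' @param stim,x a `Stimulus`.
#' @export
stimulusImage <- function(stim) stim@image

#' @describeIn Stimulus-class the grid side length in cells.
#' @export
gridSize <- function(stim) stim@gridSize

#' Gate maps of a GateStack
#' @param gates a [GateStack-class].
#' @return list of per-scale gate matrices.
#' @export
gateMaps <- function(gates) gates@xgate

#' Pyramidal activity of a network state
#' @param state a [NetworkState-class].
#' @param layer layer index, 0 (input layer) to `nScales`.
#' @return activity array of the requested layer.
#' @export
pyramidalActivity <- function(state, layer) state@Y[[layer + 1L]]

#' Convergence timestep of a network state
#' @param state a [NetworkState-class].
#' @export
convergenceTime <- function(state) state@T

#' Did the forward phase reach a fixed point?
#' @param state a [NetworkState-class].
#' @export
isConverged <- function(state) state@converged

#' Number of scales of a weight set
#' @param w a [RecurrentWeights-class] or [GateWeights-class].
#' @export
nScales <- function(w) w@nScales

#' Kernels of a recurrent weight set
#' @param w a [RecurrentWeights-class].
#' @export
recurrentKernels <- function(w) w@kernels
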