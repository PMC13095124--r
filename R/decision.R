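#' @include dynamics.R
NULL

#' Read out the retinotopic Q-value map
#'
#' Sums skip-connection projections from the input layer (1x1 convolution)
#' and every hidden layer (transposed kernels: a unit at layer l projects
#' only to the 3^l x 3^l output pixels inside its receptive field) at the
#' converged state.  Units of the output map estimate the expected reward of
#' an eye movement to the corresponding pixel.
#'
#' @param state a converged [NetworkState-class].
#' @param weights a [RecurrentWeights-class].
#' @param warn warn when the state did not converge (the map is still
#'   computed and flagged via the `"converged"` attribute).
#' @return numeric H x W matrix of Q-values, with attribute `"converged"`.
#' @export
computeQMap <- function(state, weights, warn = TRUE) {
  if (warn && !state@converged)
    warning("Q map read out from a non-converged state")
  q <- .cpp_qmap(state@Y, weights@kernels)
  attr(q, "converged") <- state@converged
  q
}

#' Select an eye-movement target from a Q map
#'
#' With probability `1 - epsilon` the greedy action (ties broken towards the
#' lowest linear index in column-major storage); with probability `epsilon`
#' a sample from the
#' Boltzmann distribution `P(a) = exp(Q_a) / sum_k exp(Q_k)` (computed with
#' max subtraction).
#'
#' @param q numeric Q-value matrix.
#' @param epsilon exploration probability in \[0, 1\].
#' @param rngSeed optional integer seed (the caller's RNG state is restored).
#' @return list with `action` (row, col), `qa` (its Q-value) and `greedy`.
#' @export
selectAction <- function(q, epsilon = 0, rngSeed = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  withSeed(rngSeed, {
    explore <- epsilon > 0 && runif(1) < epsilon
    if (explore) {
      p <- exp(q - max(q))
      idx <- sample.int(length(q), 1L, prob = as.vector(p))
    } else {
      idx <- which.max(q)  # which.max returns the first (lowest) index on ties
    }
    action <- c(row(q)[idx], col(q)[idx])
    list(action = as.integer(action), qa = q[idx], greedy = !explore)
  })
}

#' Boltzmann action probabilities
#'
#' @param q numeric Q-value matrix.
#' @return matrix of probabilities summing to 1.
#' @export
boltzmannProbs <- function(q) {
  p <- exp(q - max(q))
  p / sum(p)
}

# Is a pixel action inside the 3x3 block of a given cell?
actionHitsCell <- function(action, cell, cellPx = 3L) {
  px <- cellPixels(cell, cellPx)
  action[1] %in% px$rows && action[2] %in% px$cols
}

#' Reward and reward prediction error for a chosen action
#'
#' One unit of reward if the action lands on any pixel of the blue marker
#' cell on the cued figure, zero otherwise; the prediction error is
#' `delta = r - Q_a`.
#'
#' @param action length-2 integer pixel (row, col) on the output map.
#' @param stim the [Stimulus-class] of the trial.
#' @param qa Q-value of the chosen pixel.
#' @return list with `r` (0/1) and `delta`.
#' @export
rewardSignal <- function(action, stim, qa) {
  r <- as.numeric(actionHitsCell(action, stim@targetCell, stim@cellPx))
  list(r = r, delta = r - qa)
}
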