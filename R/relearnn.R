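#' @include decision.R
NULL

#' Propagate credit through the accessory network
#'
#' The second phase of the learning rule: a unit of credit is seeded at the
#' chosen output pixel and propagated through a linearized, transposed copy
#' of the forward network evaluated at the fixed point (every forward
#' pathway's transposed kernels multiplied by the local derivative of its
#' nonlinearity; clipped regimes transmit no credit).  Iterated until the
#' credit field converges (same tolerance and step cap as the forward
#' phase).  The converged credit field, together with the pre-synaptic
#' activity at the fixed point, yields for every kernel the exact gradient of
#' the chosen action's Q-value.
#'
#' @param state a converged [NetworkState-class].
#' @param stim the trial's [Stimulus-class] (or image array).
#' @param gates the trial's [GateStack-class] (or list of gate matrices).
#' @param weights a [RecurrentWeights-class].
#' @param action length-2 integer pixel (row, col) on the output map.
#' @param tMax accessory iteration cap (default 30).
#' @param tol convergence tolerance (default 1e-6).
#' @param bump see [phiGate()].
#' @return list with `credit` (per-layer credit on pyramidal activity),
#'   `creditPyr` / `creditVIP` (pre-activation credits of the pyramidal and
#'   VIP populations), `grads` (per-kernel gradients dQa/dw, shaped like the
#'   kernels), `iterations` and `converged`.
#' @export
accessoryPropagate <- function(state, stim, gates, weights, action,
                               tMax = 30L, tol = 1e-6, bump = FALSE) {
  inp <- prepareInputs(asImage(stim), gates, weights@nScales, bump)
  .cpp_accessory(inp$phiX, inp$phiG, weights@kernels, state@Y, state@VIPpre,
                 state@SOM, as.integer(action[1]) - 1L,
                 as.integer(action[2]) - 1L, as.integer(tMax), tol)
}

#' Apply the reward-gated local weight update
#'
#' Third phase of the learning rule: every learnable weight moves by
#' `beta * delta * (pre-synaptic activity) * (post-synaptic credit)`, with
#' shared kernels accumulating the sum over tied positions (this is what the
#' gradients returned by [accessoryPropagate()] contain).  Gate weights are
#' untouched; the structural masks (von Neumann horizontal kernels,
#' center-only input-layer kernel) are re-applied.
#'
#' @param weights a [RecurrentWeights-class].
#' @param grads the `grads` element of [accessoryPropagate()]'s result.
#' @param delta reward prediction error of the trial.
#' @param beta learning rate; either a scalar or a named vector with
#'   entries `ff2`, `fb`, `hor`, `li0`, `wskip` (per-family rates; missing
#'   names fall back to the first element).
#' @return the updated [RecurrentWeights-class].
#' @export
applyUpdate <- function(weights, grads, delta, beta) {
  if (delta == 0) return(weights)
  rate <- function(fam) {
    b <- if (!is.null(names(beta)) && fam %in% names(beta)) beta[[fam]]
         else beta[[1]]
    b * delta
  }
  k <- weights@kernels
  for (l in seq_along(k$ff2)) {
    k$ff2[[l]] <- k$ff2[[l]] + rate("ff2") * grads$ff2[[l]]
    k$fb[[l]] <- k$fb[[l]] + rate("fb") * grads$fb[[l]]
    h <- k$hor[[l]] + rate("hor") * grads$hor[[l]]
    h[!horizontalMask(dim(h)[3], dim(h)[4])] <- 0
    k$hor[[l]] <- h
  }
  li <- k$li0 + rate("li0") * grads$li0
  mask <- array(FALSE, dim(li)); mask[2, 2, , ] <- TRUE
  li[!mask] <- 0
  k$li0 <- li
  for (l in seq_along(k$wskip))
    k$wskip[[l]] <- k$wskip[[l]] + rate("wskip") * grads$wskip[[l]]
  bad <- !vapply(k, function(x) all(is.finite(unlist(x))), logical(1))
  if (any(bad))
    stop("non-finite weight update in kernel family: ",
         paste(names(k)[bad], collapse = ", "))
  weights@kernels <- k  # masks re-applied above; skip full validity rescans
  weights
}
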