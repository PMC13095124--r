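#' @include gates.R
NULL

#' Attentional modulation latency of an activity series
#'
#' The first timestep at which the series reaches 90% of its maximum;
#' invariant to positive rescaling.  Series that never rise above zero are
#' flagged (`NA`).
#'
#' @param series numeric vector of activity per timestep (t = 1, 2, ...).
#' @param threshold fraction of the maximum (default 0.9).
#' @param flagZero return `NA` for all-zero series instead of erroring.
#' @return integer timestep, or `NA` if flagged.
#' @export
modulationLatency <- function(series, threshold = 0.9, flagZero = TRUE) {
  if (length(series) == 0) stop("empty activity series")
  m <- max(series)
  if (m <= 0) {
    if (flagZero) return(NA_integer_)
    stop("activity never rises above zero")
  }
  which(series >= threshold * m)[1]
}

# Pyramidal activity of the layer-1 unit over a grid cell, per timestep.
probeSeries <- function(state, cell) {
  vapply(state@history, function(h) max(h[[2]][cell[1], cell[2], ]),
         numeric(1))
}

#' Gap effect on modulation latency at a bottleneck
#'
#' Presents bottleneck stimuli with a narrow and a wide gap (matched target
#' geometry per seed) to a trained network and measures the modulation
#' latency of layer-1 units with RFs on the target curve before (near) and
#' behind (far) the bottleneck.
#'
#' @param weights a trained [RecurrentWeights-class].
#' @param gw the matching trained [GateWeights-class] (curve task).
#' @param seeds integer vector of stimulus seeds.
#' @param narrow,wide gap sizes in cells.
#' @param tMax forward iteration cap.
#' @return data.frame with columns `seed`, `gap` ("narrow"/"wide"),
#'   `position` ("near"/"far"), `latency`.
#' @export
gapEffect <- function(weights, gw, seeds = 1:3, narrow = 1L, wide = 8L,
                      tMax = 60L) {
  rows <- list()
  for (s in seeds) {
    for (gap in c(narrow = narrow, wide = wide)) {
      bp <- generateBottleneckPair(gap, rngSeed = s)
      gates <- gateForward(bp$stimulus, gw)
      st <- runToFixedPoint(bp$stimulus, gates, weights, tMax = tMax,
                            record = TRUE)
      gapName <- if (gap == narrow) "narrow" else "wide"
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, gap = gapName,
        position = c("near", "far"),
        latency = c(modulationLatency(probeSeries(st, bp$spec@probeNear)),
                    modulationLatency(probeSeries(st, bp$spec@probeFar))))
    }
  }
  do.call(rbind, rows)
}

#' Model reaction time for an object-parsing stimulus
#'
#' The timestep at which the output-layer (Q map) response over the blue
#' target marker reaches 90% of its maximum.  Right-censored (flagged `NA`)
#' if the marker is never reached within `tMax` steps.
#'
#' @param weights a trained [RecurrentWeights-class].
#' @param gw trained object-task [GateWeights-class], or a precomputed
#'   [GateStack-class] / list of gate matrices for this stimulus.
#' @param stim an object-parsing [Stimulus-class] (cue and marker on the
#'   same object).
#' @param tMax forward iteration cap.
#' @param tol fixed-point tolerance on the pyramidal activity.
#' @return integer timestep or `NA`.
#' @export
modelRT <- function(weights, gw, stim, tMax = 60L, tol = 1e-6) {
  gates <- if (is(gw, "GateWeights")) gateForward(stim, gw) else gw
  # incremental stepping: only the Q trace over the marker block is kept,
  # so large canvases do not require a full activity history
  inp <- prepareInputs(asImage(stim), gates, weights@nScales)
  k <- weights@kernels
  st <- NULL
  px <- cellPixels(stim@targetCell, stim@cellPx)
  series <- numeric(0)
  for (t in seq_len(tMax)) {
    nxt <- if (is.null(st))
      .cpp_forward(inp$phiX, inp$phiG, k, 1L, -1, FALSE)
    else .cpp_step(inp$phiX, inp$phiG, k, st$Y, st$VIP, st$SOM)
    q <- .cpp_qmap(nxt$Y, k)
    series <- c(series, max(q[px$rows, px$cols]))
    if (!is.null(st)) {
      d <- max(vapply(seq_along(st$Y), function(i)
        max(abs(nxt$Y[[i]] - st$Y[[i]])), numeric(1)))
      if (d <= tol) break
    }
    st <- nxt
  }
  modulationLatency(series)
}

#' Standard error of a coefficient of determination
#'
#' `SE = sqrt(4 R^2 (1 - R^2)^2 (n - k - 1)^2 / ((n^2 - 1)(n + 3)))`.
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param k number of predictors.
#' @return the standard error.
#' @export
r2StandardError <- function(r2, n, k) {
  if (n <= k + 1) stop("need n > k + 1")
  sqrt(4 * r2 * (1 - r2)^2 * (n - k - 1)^2 / ((n^2 - 1) * (n + 3)))
}

#' Compare two coefficients of determination
#'
#' `SEdiff = sqrt(SE1^2 + SE2^2)`, `Z = (R1^2 - R2^2) / SEdiff`, two-sided
#' normal p-value.
#'
#' @param fitA,fitB [RTFit-class] objects fitted on the same observations.
#' @return list with `z` and `p`.
#' @export
r2DifferenceTest <- function(fitA, fitB) {
  seDiff <- sqrt(fitA@se^2 + fitB@se^2)
  if (seDiff == 0) stop("zero standard error of the difference")
  z <- (fitA@r2 - fitB@r2) / seDiff
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Regress human reaction times on model reaction times
#'
#' Removes outliers whose reciprocal RT deviates from the mean of the 1/RT
#' distribution by more than `sdCut` standard deviations, then fits ordinary
#' least squares (intercept plus model RT, k = 1).
#'
#' @param modelRTs,humanRTs paired numeric vectors.
#' @param sdCut outlier cut in standard deviations of 1/RT (default 2.5).
#' @return an [RTFit-class].
#' @export
rtRegression <- function(modelRTs, humanRTs, sdCut = 2.5) {
  stopifnot(length(modelRTs) == length(humanRTs))
  ok <- complete.cases(modelRTs, humanRTs)
  m <- modelRTs[ok]; h <- humanRTs[ok]
  inv <- 1 / h
  keep <- abs(inv - mean(inv)) <= sdCut * sd(inv)
  m <- m[keep]; h <- h[keep]
  if (length(m) <= 2) stop("need more than 2 paired observations")
  fit <- lm(h ~ m)
  r2 <- summary(fit)$r.squared
  new("RTFit", n = length(m), k = 1L, r2 = r2,
      se = r2StandardError(r2, length(m), 1L), coef = unname(coef(fit)))
}

#' Synthetic human reaction times at a target explained variance
#'
#' Affine transform of the model RTs plus Gaussian noise calibrated so the
#' expected R^2 of regressing the synthetic RTs on the model RTs equals
#' `r2`.  Used to exercise the regression machinery without external data.
#'
#' @param modelRTs numeric vector of model timesteps.
#' @param r2 target coefficient of determination (0 < r2 <= 1).
#' @param intercept,slope affine map from timesteps to milliseconds.
#' @param seed integer RNG seed.
#' @return numeric vector of synthetic RTs.
#' @export
syntheticRTs <- function(modelRTs, r2 = 0.55, intercept = 400, slope = 40,
                         seed = NULL) {
  stopifnot(r2 > 0, r2 <= 1)
  withSeed(seed, {
    signal <- intercept + slope * modelRTs
    noiseSD <- sqrt(stats::var(signal) * (1 - r2) / r2)
    signal + rnorm(length(signal), 0, noiseSD)
  })
}

#' Geodesic distance between cue and marker inside an object
#'
#' Breadth-first search over the 4-connected object mask; the shortest
#' within-object path length (in cells) from the fixation cue to the target
#' marker.  Model RTs should grow with this distance.
#'
#' @param stim an object-parsing [Stimulus-class].
#' @return integer number of steps.
#' @export
geodesicDistance <- function(stim) {
  n <- stim@gridSize
  inObj <- matrix(FALSE, n, n); inObj[stim@target] <- TRUE
  distm <- matrix(NA_integer_, n, n)
  from <- matrix(stim@fixationCell, 1)
  distm[from] <- 0L
  d <- 0L
  while (is.na(distm[stim@targetCell[1], stim@targetCell[2]]) &&
         nrow(from) > 0) {
    d <- d + 1L
    nxt <- NULL
    for (i in seq_len(nrow(from))) {
      nb <- vnNeighbors(from[i, 1], from[i, 2], n)
      nb <- nb[inObj[nb] & is.na(distm[nb]), , drop = FALSE]
      if (nrow(nb)) { distm[nb] <- d; nxt <- rbind(nxt, nb) }
    }
    from <- if (is.null(nxt)) matrix(0L, 0, 2) else unique(nxt)
  }
  distm[stim@targetCell[1], stim@targetCell[2]]
}
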