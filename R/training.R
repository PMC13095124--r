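#' @include relearnn.R analysis.R
NULL

#' Trainer configuration for the reinforcement-learning phases
#'
#' @slot beta learning rate of the reward-gated update.
#' @slot negScale extra multiplier on the horizontal kernels' rate for
#'   negative-prediction-error trials (1 = symmetric).
#' @slot horRate multiplier on `beta` for the horizontal kernels.
#' @slot horRateFrom curriculum length from which `horRate` applies.
#' @slot epsilon exploration probability (Boltzmann sampling); 0 during test
#'   phases.
#' @slot tMax forward / accessory iteration cap (30).
#' @slot tol fixed-point tolerance (1e-6).
#' @slot seed integer RNG seed of the whole training run.
#' @slot startLength,endLength curriculum curve lengths (3 and 7).
#' @slot criterion frozen-test accuracy required to advance a stage (0.85).
#' @slot finalAccuracy frozen-test accuracy at which training at the last
#'   stage stops (1.0: train to convergence).
#' @slot testEvery training trials between frozen test phases.
#' @slot nTest trials per frozen test.
#' @slot poolSize training stimuli drawn per curriculum stage.
#' @slot maxTrialsPerStage trial budget per stage attempt.
#' @slot stageRetries extra attempts per stage (fresh stimulus pools,
#'   restarting from the best-tested weights) before giving up.
#' @slot maxMinutes wall-clock cap on a whole training run; when exceeded,
#'   training stops and returns the best-tested network.
#' @exportClass TrainerConfig
setClass("TrainerConfig", representation(
  beta = "numeric", negScale = "numeric", horRate = "numeric",
  horRateFrom = "integer", epsilon = "numeric", tMax = "integer",
  tol = "numeric",
  seed = "integer", startLength = "integer", endLength = "integer",
  criterion = "numeric", finalAccuracy = "numeric", testEvery = "integer",
  nTest = "integer", poolSize = "integer", maxTrialsPerStage = "integer",
  stageRetries = "integer", maxMinutes = "numeric"))

#' Create a trainer configuration
#'
#' @param beta learning rate (default 0.01).
#' @param negScale additional multiplier on the horizontal kernels' rate
#'   for negative-prediction-error trials (default 0.5).  When a curriculum
#'   stage begins, error floods would otherwise tear down the shared
#'   disinhibition chains that earlier stages built, collapsing the network;
#'   failures should re-tune drives and readout, not the propagation
#'   infrastructure.
#' @param horRate multiplier on `beta` for the horizontal kernels (default
#'   10), applied from curriculum length `horRateFrom` (default 6) onward.
#'   The credit a horizontal synapse receives is the product of the small
#'   derivatives along the disinhibition chain, much smaller than the credit
#'   of feedforward synapses; without a faster rate the feedforward drive
#'   out-runs the chains and propagation never becomes self-sustaining, so
#'   the curriculum stalls at 5-6 cells.  Applying the fast rate from the
#'   start instead destabilizes the discrimination phase (short curves are
#'   solved by drive asymmetry while the chains are still nascent), so it is
#'   switched on only once the curriculum exceeds the initial chains' reach.
#' @param horRateFrom see `horRate`.
#' @param epsilon exploration probability (default 0.05).
#' @param tMax,tol forward/accessory iteration cap and tolerance.
#' @param seed integer RNG seed.
#' @param startLength,endLength curriculum limits (3 and 7 cells).
#' @param criterion stage-advancement accuracy (0.85).
#' @param finalAccuracy stopping accuracy at the final stage (1.0).
#' @param testEvery,nTest test-phase cadence and size.
#' @param poolSize stimuli generated per curriculum stage.
#' @param maxTrialsPerStage per-stage trial budget (per attempt).
#' @param stageRetries extra attempts per stage.  The trial-and-error
#'   trajectory occasionally collapses when a new stage begins (an error
#'   flood erodes the shared weights faster than the prediction error
#'   settles); a collapsed attempt is abandoned and the stage restarts from
#'   the best weights tested so far, with freshly generated stimuli.
#' @param maxMinutes wall-clock cap on the whole run (default `Inf`); when
#'   exceeded the curriculum stops and the best-tested network is returned.
#' @return a [TrainerConfig-class].
#' @export
trainerConfig <- function(beta = 0.01, negScale = 1, horRate = 10,
                          horRateFrom = 6L,
                          epsilon = 0.05, tMax = 30L,
                          tol = 1e-6, seed = 1L, startLength = 3L,
                          endLength = 7L, criterion = 0.85,
                          finalAccuracy = 1.0, testEvery = 100L,
                          nTest = 100L, poolSize = 300L,
                          maxTrialsPerStage = 30000L, stageRetries = 2L,
                          maxMinutes = Inf) {
  stopifnot(beta > 0, negScale > 0, horRate > 0, epsilon >= 0, epsilon <= 1)
  new("TrainerConfig", beta = beta, negScale = negScale, horRate = horRate,
      horRateFrom = as.integer(horRateFrom), epsilon = epsilon,
      tMax = as.integer(tMax), tol = tol, seed = as.integer(seed),
      startLength = as.integer(startLength),
      endLength = as.integer(endLength), criterion = criterion,
      finalAccuracy = finalAccuracy, testEvery = as.integer(testEvery),
      nTest = as.integer(nTest), poolSize = as.integer(poolSize),
      maxTrialsPerStage = as.integer(maxTrialsPerStage),
      stageRetries = as.integer(stageRetries), maxMinutes = maxMinutes)
}

setMethod("show", "TrainerConfig", function(object) {
  cat(sprintf(paste0("TrainerConfig: beta %.4g, epsilon %.2f, curriculum ",
                     "%d..%d cells, criterion %.2f\n"), object@beta,
              object@epsilon, object@startLength, object@endLength,
              object@criterion))
})

# Compact pool entry for fast trial loops: phi-transformed cell-level image,
# phi-transformed gate maps, and the reward geometry.
poolEntry <- function(stim, gw, nScales, bump = FALSE) {
  img <- padImage(stim@image, nScales)
  G <- nrow(img) %/% stim@cellPx
  grid <- array(0, c(G, G, 3))
  cp <- stim@cellPx
  grid[seq_len(stim@gridSize), seq_len(stim@gridSize), ] <-
    stim@image[seq(1L, stim@gridSize * cp, by = cp),
               seq(1L, stim@gridSize * cp, by = cp), ]
  gates <- gateForward(img, gw)
  list(phiGrid = phiGate(grid, bump),
       phiG = lapply(gates@xgate, phiGate, bump = bump),
       targetCell = stim@targetCell, distractorCell = stim@distractorCell,
       cellPx = cp)
}

makePool <- function(n, gen, gw, nScales) {
  lapply(seq_len(n), function(i) poolEntry(gen(), gw, nScales))
}

# One trial on a pool entry.  Returns the (possibly updated) kernels and the
# trial record fields.
poolTrial <- function(entry, weights, cfg, epsilon, learn = TRUE) {
  phiX <- expandCells(entry$phiGrid, entry$cellPx)
  fw <- .cpp_forward(phiX, entry$phiG, weights@kernels, cfg@tMax, cfg@tol,
                     FALSE)
  q <- .cpp_qmap(fw$Y, weights@kernels)
  explore <- epsilon > 0 && runif(1) < epsilon
  if (explore) {
    p <- exp(q - max(q))
    idx <- sample.int(length(q), 1L, prob = as.vector(p))
  } else idx <- which.max(q)
  action <- c(row(q)[idx], col(q)[idx])
  r <- as.numeric(actionHitsCell(action, entry$targetCell, entry$cellPx))
  delta <- r - q[idx]
  if (learn && delta != 0) {
    acc <- .cpp_accessory(phiX, entry$phiG, weights@kernels, fw$Y, fw$VIPpre,
                          fw$SOM, action[1] - 1L, action[2] - 1L, cfg@tMax,
                          cfg@tol)
    b <- cfg@beta
    bh <- b * cfg@horRate * (if (delta < 0) cfg@negScale else 1)
    weights <- applyUpdate(weights, acc$grads, delta,
                           c(ff2 = b, fb = b, hor = bh, li0 = b, wskip = b))
  }
  list(weights = weights, r = r, delta = delta, qa = q[idx], T = fw$T,
       greedy = !explore)
}

frozenTest <- function(pool, weights, cfg) {
  hits <- vapply(pool, function(e)
    poolTrial(e, weights, cfg, epsilon = 0, learn = FALSE)$r, numeric(1))
  mean(hits)
}

# One curriculum stage.  A frozen test precedes any training (a network that
# already meets the criterion advances untouched: training on a mastered
# stage erodes it before the prediction error settles).  The best-tested
# weights are tracked; on budget exhaustion the stage either aborts
# (curriculum advancement: the criterion is a hard gate) or returns the best
# weights seen (final consolidation toward perfect accuracy).
runStage <- function(weights, trainPool, testPool, cfg, stage,
                     stopAccuracy, log, verbose = FALSE,
                     deadline = Inf) {
  trials <- 0L
  testSet <- testPool[seq_len(min(cfg@nTest, length(testPool)))]
  acc <- frozenTest(testSet, weights, cfg)
  log[[length(log) + 1L]] <- data.frame(stage = stage, trials = trials,
                                        accuracy = acc, reward = NA_real_,
                                        meanAbsDelta = NA_real_,
                                        maxQa = NA_real_)
  if (verbose)
    message(sprintf("  %s: entry test accuracy %.0f%%", stage, 100 * acc))
  best <- list(weights = weights, accuracy = acc)
  while (acc < stopAccuracy) {
    if (trials >= cfg@maxTrialsPerStage || Sys.time() > deadline) {
      if (verbose)
        message(sprintf("  %s: budget reached; best tested %.0f%%",
                        stage, 100 * best$accuracy))
      return(list(weights = best$weights, trials = trials,
                  accuracy = best$accuracy, log = log, passed = FALSE))
    }
    deltas <- numeric(cfg@testEvery); qas <- numeric(cfg@testEvery)
    for (i in seq_len(cfg@testEvery)) {
      e <- trainPool[[sample.int(length(trainPool), 1L)]]
      res <- poolTrial(e, weights, cfg, cfg@epsilon, learn = TRUE)
      weights <- res$weights
      deltas[i] <- res$delta; qas[i] <- res$qa
      trials <- trials + 1L
    }
    acc <- frozenTest(testSet, weights, cfg)
    if (acc > best$accuracy) best <- list(weights = weights, accuracy = acc)
    log[[length(log) + 1L]] <- data.frame(stage = stage, trials = trials,
                                          accuracy = acc,
                                          reward = mean(deltas + qas),
                                          meanAbsDelta = mean(abs(deltas)),
                                          maxQa = max(qas))
    if (verbose)
      message(sprintf(
        "  %s: %d trials, test accuracy %.0f%% (reward %.2f, |delta| %.2f, maxQ %.2f)",
        stage, trials, 100 * acc, mean(deltas + qas), mean(abs(deltas)),
        max(qas)))
  }
  list(weights = weights, trials = trials, accuracy = acc, log = log,
       passed = TRUE)
}

# Run a stage with bounded retries: a failed attempt restarts from the best
# weights tested so far, on freshly generated pools.
runStageRetrying <- function(weights, poolGen, cfg, stage, stopAccuracy, log,
                             verbose, gw, deadline = Inf) {
  total <- 0L
  best <- list(weights = weights, accuracy = -1)
  for (attempt in 0:cfg@stageRetries) {
    trainPool <- makePool(cfg@poolSize, poolGen, gw, gw@nScales)
    testPool <- makePool(cfg@nTest, poolGen, gw, gw@nScales)
    tag <- if (attempt == 0) stage else sprintf("%s-retry%d", stage, attempt)
    res <- runStage(best$weights, trainPool, testPool, cfg, tag,
                    stopAccuracy, log, verbose = verbose, deadline = deadline)
    log <- res$log; total <- total + res$trials
    if (res$accuracy > best$accuracy)
      best <- list(weights = res$weights, accuracy = res$accuracy)
    if (res$passed)
      return(list(weights = res$weights, trials = total,
                  accuracy = res$accuracy, log = log, passed = TRUE))
    if (Sys.time() > deadline) break
  }
  list(weights = best$weights, trials = total, accuracy = best$accuracy,
       log = log, passed = FALSE)
}

#' Train the recurrent network on the curve-tracing task
#'
#' Runs the reinforcement-learning curriculum: starting with 3-cell curves,
#' each trial generates a stimulus, iterates the network to its fixed point,
#' selects an eye movement, collects the reward, propagates credit through
#' the accessory network and applies the local reward-gated update.  After
#' every `testEvery` trials a frozen test (no exploration, no learning) is
#' run; at 85% accuracy the curve grows by one cell, up to `endLength`
#' cells.  At the final length, training continues to `finalAccuracy`
#' (networks reach 100%).  Stimuli are drawn from per-stage pools of
#' `poolSize` freshly generated curve pairs; test pools are disjoint.
#'
#' @param gw a trained, frozen curve-task [GateWeights-class].
#' @param cfg a [TrainerConfig-class].
#' @param weights optional starting [RecurrentWeights-class] (default: fresh
#'   initialization from `cfg@seed`).
#' @param gridSize stimulus grid side (36).
#' @param verbose print per-stage progress.
#' @param onFailure `"abort"` stops with diagnostics when a curriculum stage
#'   exhausts its attempts; `"return"` instead returns the best network
#'   reached so far (the log records the failure).
#' @return list with `weights`, `log` (test-phase accuracies), `trials`
#'   (total training trials), and `completed` (did every stage meet its
#'   criterion).
#' @export
trainCurveTask <- function(gw, cfg = trainerConfig(), weights = NULL,
                           gridSize = 36L, verbose = FALSE,
                           onFailure = c("abort", "return")) {
  onFailure <- match.arg(onFailure)
  deadline <- Sys.time() + 60 * cfg@maxMinutes
  withSeed(cfg@seed, {
    if (is.null(weights)) weights <- newRecurrentWeights(gw@nScales)
    log <- list()
    total <- 0L
    completed <- TRUE
    for (len in cfg@startLength:cfg@endLength) {
      gen <- local({ ln <- len; function() generateCurvePair(gridSize, ln) })
      final <- len == cfg@endLength
      stageCfg <- cfg
      if (len < cfg@horRateFrom) stageCfg@horRate <- 1
      res <- runStageRetrying(weights, gen, stageCfg,
                              sprintf("length-%d", len), cfg@criterion, log,
                              verbose, gw, deadline)
      weights <- res$weights; log <- res$log; total <- total + res$trials
      if (!res$passed && Sys.time() > deadline) {
        completed <- FALSE
        if (verbose)
          message(sprintf("length %d: time budget reached; stopping", len))
        break
      }
      if (!res$passed) {
        # criterion not met within the attempt budget
        if (onFailure == "abort")
          stop(sprintf(
            "stage 'length-%d' failed to reach %.0f%% in %d attempts of %d trials",
            len, 100 * cfg@criterion, cfg@stageRetries + 1L,
            cfg@maxTrialsPerStage))
        completed <- FALSE
        if (verbose)
          message(sprintf("length %d: criterion not met; stopping curriculum",
                          len))
        break
      }
      if (final && cfg@finalAccuracy > cfg@criterion) {
        # consolidation at the final length: continue toward perfect
        # accuracy, keeping the best-tested weights
        res <- runStageRetrying(weights, gen, stageCfg,
                                sprintf("length-%d-final", len),
                                cfg@finalAccuracy, res$log, verbose, gw,
                                deadline)
        weights <- res$weights; log <- res$log; total <- total + res$trials
      }
      if (verbose)
        message(sprintf("length %d: %d trials, test accuracy %.0f%%", len,
                        res$trials, 100 * res$accuracy))
    }
    list(weights = weights, log = do.call(rbind, log), trials = total,
         completed = completed)
  })
}

#' Retrain a curve-trained network on the object-parsing task
#'
#' Substitutes object-task gates and continues the same reinforcement
#' learning on two-object stimuli.  Tests every `testEvery` trials; stops
#' when the frozen-test accuracy reaches `criterion` or after `maxTrials`
#' training trials.
#'
#' @param weights a curve-trained [RecurrentWeights-class].
#' @param gw a trained object-task [GateWeights-class].
#' @param cfg a [TrainerConfig-class] (`testEvery` is also the retraining
#'   test cadence).
#' @param maxTrials retraining budget (100).
#' @param gridSize object grid side (72).
#' @param verbose print progress.
#' @return list with `weights`, `trials` used, `accuracy` (final frozen
#'   test), and `log`.
#' @export
retrainObjectTask <- function(weights, gw, cfg = trainerConfig(),
                              maxTrials = 100L, gridSize = 72L,
                              verbose = FALSE) {
  withSeed(cfg@seed + 1L, {
    cfg@horRate <- 1  # chains are already consolidated after curve training
    trainPool <- makePool(max(50L, maxTrials %/% 2L),
                          function() generateObjectPair(gridSize),
                          gw, gw@nScales)
    testPool <- makePool(cfg@nTest,
                         function() generateObjectPair(gridSize),
                         gw, gw@nScales)
    log <- list()
    trials <- 0L
    acc <- frozenTest(testPool, weights, cfg)
    log[[1L]] <- data.frame(stage = "object", trials = 0L, accuracy = acc)
    best <- list(weights = weights, accuracy = acc, trials = 0L)
    block <- 20L  # test often: the useful transfer can appear and vanish
    while (acc < cfg@criterion && trials < maxTrials) {
      for (i in seq_len(min(block, maxTrials - trials))) {
        e <- trainPool[[sample.int(length(trainPool), 1L)]]
        res <- poolTrial(e, weights, cfg, cfg@epsilon, learn = TRUE)
        weights <- res$weights
        trials <- trials + 1L
      }
      acc <- frozenTest(testPool, weights, cfg)
      if (acc > best$accuracy)
        best <- list(weights = weights, accuracy = acc, trials = trials)
      log[[length(log) + 1L]] <- data.frame(stage = "object",
                                            trials = trials, accuracy = acc)
      if (verbose)
        message(sprintf("object retraining: %d trials, accuracy %.0f%%",
                        trials, 100 * acc))
    }
    if (acc < best$accuracy) {
      # keep the best-tested network seen during retraining
      weights <- best$weights; acc <- best$accuracy; trials <- best$trials
    }
    list(weights = weights, trials = trials, accuracy = acc,
         log = do.call(rbind, log))
  })
}

#' Frozen-weight evaluation on a set of stimuli
#'
#' Runs each stimulus to its fixed point, selects the greedy action
#' (no exploration) and scores it against the ground-truth target marker.
#'
#' @param weights a [RecurrentWeights-class].
#' @param gw the matching [GateWeights-class].
#' @param stimuli list of [Stimulus-class] objects.
#' @param cfg a [TrainerConfig-class] (iteration cap / tolerance).
#' @return accuracy in \[0, 1\], with per-trial hits as attribute `"hits"`.
#' @export
evaluateNetwork <- function(weights, gw, stimuli, cfg = trainerConfig()) {
  hits <- vapply(stimuli, function(s) {
    e <- poolEntry(s, gw, gw@nScales)
    poolTrial(e, weights, cfg, epsilon = 0, learn = FALSE)$r
  }, numeric(1))
  structure(mean(hits), hits = hits)
}

#' Run a single reinforcement-learning trial
#'
#' Forward phase to the fixed point, action selection, reward; optionally
#' the accessory phase and weight update.  Mainly a convenience for
#' inspecting single trials; the trainers run this loop internally.
#'
#' @param stim a [Stimulus-class].
#' @param gw the matching [GateWeights-class] (or a precomputed
#'   [GateStack-class]).
#' @param weights a [RecurrentWeights-class].
#' @param cfg a [TrainerConfig-class].
#' @param learn apply the reward-gated update.
#' @return list with `record` (a [TrialRecord-class]) and `weights` (updated
#'   when `learn = TRUE`).
#' @export
runTrial <- function(stim, gw, weights, cfg = trainerConfig(),
                     learn = FALSE) {
  gates <- if (is(gw, "GateWeights")) gateForward(stim, gw) else gw
  xg <- if (is(gates, "GateStack")) gates@xgate else gates
  e <- list(phiGrid = NULL, phiG = lapply(xg, phiGate),
            targetCell = stim@targetCell,
            distractorCell = stim@distractorCell, cellPx = stim@cellPx)
  inp <- prepareInputs(stim@image, xg, weights@nScales)
  fw <- .cpp_forward(inp$phiX, inp$phiG, weights@kernels, cfg@tMax, cfg@tol,
                     FALSE)
  q <- .cpp_qmap(fw$Y, weights@kernels)
  sel <- selectAction(q, cfg@epsilon)
  rs <- rewardSignal(sel$action, stim, sel$qa)
  if (learn && rs$delta != 0) {
    acc <- .cpp_accessory(inp$phiX, inp$phiG, weights@kernels, fw$Y,
                          fw$VIPpre, fw$SOM, sel$action[1] - 1L,
                          sel$action[2] - 1L, cfg@tMax, cfg@tol)
    b <- cfg@beta
    bh <- b * cfg@horRate * (if (rs$delta < 0) cfg@negScale else 1)
    weights <- applyUpdate(weights, acc$grads, rs$delta,
                           c(ff2 = b, fb = b, hor = bh, li0 = b, wskip = b))
  }
  rec <- new("TrialRecord", action = as.integer(sel$action), qa = sel$qa,
             reward = rs$r, delta = rs$delta, T = as.integer(fw$T),
             greedy = sel$greedy)
  list(record = rec, weights = weights)
}

setMethod("show", "TrialRecord", function(object) {
  cat(sprintf(
    "TrialRecord: action (%d,%d)%s, Q = %.3f, r = %g, delta = %+.3f, T = %d\n",
    object@action[1], object@action[2],
    if (object@greedy) " (greedy)" else " (explored)", object@qa,
    object@reward, object@delta, object@T))
})
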