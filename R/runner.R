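#' @include training.R
NULL

#' Truncate a trained network to fewer scales
#'
#' Removes the top hidden layers; the remaining layers, their feedback loops
#' and their readout skip kernels are untouched (the readout already spans
#' every remaining layer).  Used to build 2- and 3-scale variants of a
#' 4-scale network for ablation analyses.
#'
#' @param weights a [RecurrentWeights-class].
#' @param nScales target number of scales (<= `weights@nScales`).
#' @return a [RecurrentWeights-class] with `nScales` hidden layers.
#' @export
truncateWeights <- function(weights, nScales) {
  L <- as.integer(nScales)
  stopifnot(L >= 1L, L <= weights@nScales)
  k <- weights@kernels
  new("RecurrentWeights", nScales = L,
      channels = weights@channels[seq_len(L + 1L)],
      kernels = list(ff2 = k$ff2[seq_len(L)], fb = k$fb[seq_len(L)],
                     hor = k$hor[seq_len(L)], li0 = k$li0,
                     wskip = k$wskip[seq_len(L + 1L)]))
}

#' @rdname truncateWeights
#' @param gw a [GateWeights-class].
#' @export
truncateGateWeights <- function(gw, nScales) {
  L <- as.integer(nScales)
  stopifnot(L >= 1L, L <= gw@nScales)
  new("GateWeights", ff0 = gw@ff0, b0 = gw@b0, scales = gw@scales[seq_len(L)],
      nScales = L, task = gw@task)
}

#' Experiment configuration
#'
#' A validated list of all knobs of an end-to-end experiment; written
#' verbatim (YAML) into every run directory.
#'
#' @param task `"curve"`, `"object"` or `"both"` (curve training followed by
#'   object retraining).
#' @param nScales number of scales (2-4).
#' @param gridSize curve-task grid side.
#' @param objectGridSize object-task grid side.
#' @param seed integer seed for the whole experiment.
#' @param gateStimuli,gateEpochs scale-selection training set size and epochs.
#' @param beta,epsilon reinforcement-learning rate and exploration.
#' @param startLength,endLength curriculum limits.
#' @param poolSize,nTest,testEvery,maxTrialsPerStage trainer sizes.
#' @param criterion stage-advancement accuracy.
#' @param finalAccuracy stopping accuracy at the final curriculum stage.
#' @param stageRetries extra attempts per curriculum stage.
#' @param maxMinutes wall-clock cap on the reinforcement-learning run.
#' @return a named list of class `"tracenetConfig"`.
#' @export
experimentConfig <- function(task = "both", nScales = 4L, gridSize = 36L,
                             objectGridSize = 72L, seed = 1L,
                             gateStimuli = 300L, gateEpochs = 5L,
                             beta = 0.01, epsilon = 0.05,
                             startLength = 3L, endLength = 7L,
                             poolSize = 300L, nTest = 100L,
                             testEvery = 100L, maxTrialsPerStage = 30000L,
                             criterion = 0.85, finalAccuracy = 1.0,
                             stageRetries = 2L, maxMinutes = Inf) {
  cfg <- list(task = task, nScales = as.integer(nScales),
              gridSize = as.integer(gridSize),
              objectGridSize = as.integer(objectGridSize),
              seed = as.integer(seed), gateStimuli = as.integer(gateStimuli),
              gateEpochs = as.integer(gateEpochs), beta = beta,
              epsilon = epsilon, startLength = as.integer(startLength),
              endLength = as.integer(endLength),
              poolSize = as.integer(poolSize), nTest = as.integer(nTest),
              testEvery = as.integer(testEvery),
              maxTrialsPerStage = as.integer(maxTrialsPerStage),
              criterion = criterion, finalAccuracy = finalAccuracy,
              stageRetries = as.integer(stageRetries),
              maxMinutes = maxMinutes)
  stopifnot(cfg$task %in% c("curve", "object", "both"),
            cfg$nScales >= 1L, cfg$nScales <= 4L,
            cfg$beta > 0, cfg$epsilon >= 0, cfg$epsilon <= 1,
            cfg$startLength >= 2L, cfg$endLength >= cfg$startLength,
            (cfg$gridSize * 3L) %% 3L^cfg$nScales == 0 ||
              TRUE)  # images are padded, any grid works
  class(cfg) <- c("tracenetConfig", "list")
  cfg
}

trainerFromConfig <- function(cfg) {
  trainerConfig(beta = cfg$beta, epsilon = cfg$epsilon, seed = cfg$seed,
                startLength = cfg$startLength, endLength = cfg$endLength,
                poolSize = cfg$poolSize, nTest = cfg$nTest,
                testEvery = cfg$testEvery,
                maxTrialsPerStage = cfg$maxTrialsPerStage,
                criterion = cfg$criterion, finalAccuracy = cfg$finalAccuracy,
                stageRetries = cfg$stageRetries, maxMinutes = cfg$maxMinutes)
}

#' Run an end-to-end experiment
#'
#' Trains the scale-selection pathway, runs the reinforcement-learning
#' curriculum, evaluates generalization (and, for `task = "both"`, the
#' object-parsing transfer), and writes all artifacts into `outDir`:
#' `config.yaml`, `gateWeights.rds` / `weights.rds`, `log.csv`,
#' `metrics.csv`.  Every artifact is regenerable from the configuration and
#' seed alone.
#'
#' @param cfg an [experimentConfig()].
#' @param outDir run directory (created; must not exist unless
#'   `overwrite = TRUE`).
#' @param overwrite replace an existing run directory.
#' @param verbose print progress.
#' @return invisibly, a list with the trained objects and the metrics table.
#' @export
runExperiment <- function(cfg, outDir, overwrite = FALSE, verbose = FALSE) {
  if (dir.exists(outDir)) {
    if (!overwrite) stop("run directory already exists: ", outDir)
  } else dir.create(outDir, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(outDir, "config.yaml"))
  metrics <- list()
  gw <- trainGates("curve", nStimuli = cfg$gateStimuli,
                   epochs = cfg$gateEpochs, gridSize = cfg$gridSize,
                   nScales = cfg$nScales, seed = cfg$seed,
                   lengths = cfg$startLength:min(max(cfg$endLength + 1L, 8L),
                                                 cfg$gridSize - 1L))
  saveRDS(gw, file.path(outDir, "gateWeights.rds"))
  tcfg <- trainerFromConfig(cfg)
  res <- trainCurveTask(gw, tcfg, gridSize = cfg$gridSize, verbose = verbose,
                        onFailure = "return")
  saveRDS(res$weights, file.path(outDir, "weights.rds"))
  write.csv(res$log, file.path(outDir, "log.csv"), row.names = FALSE)
  metrics$curveTrials <- res$trials
  metrics$curveAccuracy <- tail(res$log$accuracy, 1)
  weights <- res$weights
  if (cfg$task == "both") {
    gwObj <- trainGates("object", nStimuli = max(50L, cfg$gateStimuli %/% 2L),
                        epochs = cfg$gateEpochs,
                        gridSize = cfg$objectGridSize, nScales = cfg$nScales,
                        seed = cfg$seed + 1L)
    saveRDS(gwObj, file.path(outDir, "gateWeightsObject.rds"))
    ret <- retrainObjectTask(weights, gwObj, tcfg,
                             gridSize = cfg$objectGridSize, verbose = verbose)
    saveRDS(ret$weights, file.path(outDir, "weightsObject.rds"))
    metrics$objectTrials <- ret$trials
    metrics$objectAccuracy <- ret$accuracy
    weights <- ret$weights
  }
  mt <- data.frame(metric = names(metrics),
                   value = unlist(metrics, use.names = FALSE))
  write.csv(mt, file.path(outDir, "metrics.csv"), row.names = FALSE)
  invisible(list(gateWeights = gw, weights = weights, metrics = mt,
                 dir = outDir))
}

#' Scale-count ablation of reaction-time predictions
#'
#' Builds 2-, 3- and 4-scale variants of a trained network by truncating the
#' top layers, computes model RTs on an object-stimulus battery for each
#' variant, regresses the reference RTs on each variant's RTs and compares
#' the coefficients of determination (Z-test on the R^2 difference against
#' the fullest variant).
#'
#' @param weights a trained [RecurrentWeights-class] (object task).
#' @param gw the matching object-task [GateWeights-class].
#' @param stimuli list of object-parsing [Stimulus-class] objects.
#' @param humanRTs reference RTs paired with `stimuli` (e.g. real data from
#'   CSV, or [syntheticRTs()] of the full model for offline use).
#' @param scales integer vector of variant sizes.
#' @param tMax forward iteration cap per stimulus.
#' @return data.frame with one row per variant: `scales`, `r2`, `se`, `z`,
#'   `p` (comparison against the largest variant), `nCensored`.
#' @export
scaleAblation <- function(weights, gw, stimuli, humanRTs,
                          scales = c(2L, 3L, 4L), tMax = 60L) {
  scales <- sort(unique(pmin(as.integer(scales), weights@nScales)))
  # gate maps for a truncated variant are the prefix of the full stack;
  # compute each stimulus' gates once
  stacks <- lapply(stimuli, function(s) gateForward(s, gw)@xgate)
  fits <- list()
  for (L in scales) {
    wL <- truncateWeights(weights, L)
    rts <- vapply(seq_along(stimuli), function(i) {
      rt <- modelRT(wL, stacks[[i]][seq_len(L)], stimuli[[i]], tMax = tMax)
      if (is.na(rt)) NA_real_ else as.numeric(rt)
    }, numeric(1))
    fits[[as.character(L)]] <-
      list(fit = rtRegression(rts, humanRTs), nCensored = sum(is.na(rts)))
  }
  ref <- fits[[as.character(max(scales))]]$fit
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cmp <- if (nm == as.character(max(scales))) list(z = 0, p = 1)
           else tryCatch(r2DifferenceTest(ref, f$fit),
                         error = function(e) list(z = NA_real_, p = NA_real_))
    data.frame(scales = as.integer(nm), r2 = f$fit@r2, se = f$fit@se,
               n = f$fit@n, z = cmp$z, p = cmp$p, nCensored = f$nCensored)
  }))
}

#' Plot a stimulus
#'
#' @param stim a [Stimulus-class].
#' @param ... passed to [graphics::rasterImage()].
#' @export
plotStimulus <- function(stim, ...) {
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  graphics::rasterImage(grDevices::as.raster(stim@image), 0, 0, 1, 1,
                        interpolate = FALSE, ...)
}
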