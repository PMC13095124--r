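# Expensive trained fixtures, built once per test session and shared across
# test files (test-acceptance runs first alphabetically and warms these).

# Desk-scale study settings used by both the test suite and the worked
# examples: sizes chosen so the full pipeline trains in minutes on one core.
deskGateSettings <- function(task) {
  if (task == "curve")
    list(nStimuli = 350L, epochs = 7L, lr = 1e-3,
         perStim = c(6L, 6L, 4L, 4L), seed = 101L)
  else
    list(nStimuli = 150L, epochs = 7L, lr = 1e-3,
         perStim = c(6L, 6L, 4L, 4L), seed = 202L)
}

trainedCurveGates <- function() {
  cached("curveGates", {
    s <- deskGateSettings("curve")
    trainGates("curve", nStimuli = s$nStimuli, epochs = s$epochs, lr = s$lr,
               perStim = s$perStim, seed = s$seed)
  })
}

trainedObjectGates <- function() {
  cached("objectGates", {
    s <- deskGateSettings("object")
    trainGates("object", nStimuli = s$nStimuli, epochs = s$epochs, lr = s$lr,
               perStim = s$perStim, seed = s$seed)
  })
}

deskTrainerConfig <- function(seed = 1L) {
  trainerConfig(beta = 0.01, epsilon = 0.05, seed = seed, poolSize = 150L,
                nTest = 60L, testEvery = 100L, maxTrialsPerStage = 4000L,
                stageRetries = 2L, maxMinutes = 7.5)
}

trainedCurveNetwork <- function() {
  cached("curveNetwork", {
    gw <- trainedCurveGates()
    trainCurveTask(gw, deskTrainerConfig(seed = 1L), onFailure = "return")
  })
}
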