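# tracenet

Multiscale recurrent networks for incremental perceptual grouping in R.

## The problem

When you decide whether a dot lies on the same curve as a fixation point —
or whether two points sit on the same object — your visual system labels the
cued figure piece by piece: neurons in visual cortex whose receptive fields
(RFs) fall on the cued curve gradually enhance their firing, starting at the
cue and spreading along the curve.  The spread is fast where the target is
far from any distractor (large RFs in higher areas can carry it) and slow
where the figures come close (only small RFs avoid covering both).
`tracenet` implements this *growth-cone* account of object-based attention
as a trainable neural network, for computational neuroscientists who want a
mechanistic, learnable model of incremental grouping whose dynamics can be
compared with monkey electrophysiology and human reaction times.

## The model

Two pathways operate on an RGB raster stimulus (curves or filled objects on
a grid; a red cell is the fixation cue, blue cells are candidate saccade
targets):

* **Scale selection (feedforward).**  At scales `l = 1..4` with RF side
  `3^l` pixels, a small convolutional detector reports whether its RF's
  content is *unambiguous*: for curves, a single straight connected run of
  one curve; for objects, full coverage by one object.
  `gate_l = ReLU(sigmoid(FFout_l * ReLU(FFint_l * ReLU(FF0 * X))) - 0.7)`.
  Trained supervised against exact geometry-derived labels, then frozen.
* **Incremental grouping (recurrent).**  Layers at resolutions `H/3^l` hold
  pyramidal units plus VIP and SOM interneurons.  SOM cells are tonically
  active and clamp the pyramidal drive; VIP cells, driven by horizontal
  (von Neumann neighborhood) and top-down connections, inhibit SOM cells
  and thereby *disinhibit* pyramidal cells:

  `VIP_l(t) = clip01(Hor_l * Y_l(t-1) + FB_l *^T Y_{l+1}(t-1))`
  `SOM_l(t) = ReLU(1 - VIP_l(t))`
  `Y_l(t) = ReLU(phi(gate_l) . (FF2_l * Y_{l-1}(t) - SOM_l(t)))`

  Enhancement can only be *released*, never added, so activity is bounded
  by the gated feedforward drive for any weights, and the iteration reaches
  a stable state (at most 30 steps, tolerance 1e-6).  A retinotopic Q-value
  map is read out through skip connections from every layer; the action is
  the Q-argmax (Boltzmann exploration with probability 0.05 during
  training); reward is 1 iff the chosen pixel is the blue marker on the
  cued figure.
* **Learning (three-phase, local).**  After the forward phase and action
  selection, an *accessory network* — the linearized, transposed forward
  network at the fixed point — propagates credit from the chosen output
  unit; each synapse then updates by
  `beta * delta * (presynaptic activity) * (postsynaptic credit)`, with
  `delta = r - Q_a` the reward prediction error.  The test suite verifies
  this update equals `beta * delta * dQ_a/dw` by central finite differences
  for every kernel family.

Training uses a curriculum (curves of 3 cells, +1 cell at 85% frozen-test
accuracy, to 7 cells), then transfers to object parsing by swapping in
object-task gates for at most 100 retraining trials.

## Worked example

```r
library(tracenet)

## a bottleneck stimulus: straight target curve, distractor approaching
## to 8 cells inside a central window, exact ground truth recorded
bp <- generateBottleneckPair(gapCells = 8, rngSeed = 3)
stim <- bp$stimulus
stim
#> Stimulus (curve task): 36x36 grid, 108x108 px
#>   cue (15,10) -> target (15,36); distractor marker (6,36)
#>   figure sizes: 27 / 29 cells

## a hand-built single-scale network that traces one cell per timestep
## (red cue overcomes SOM inhibition; saturating horizontal weights
## disinhibit the next cell)
w <- newRecurrentWeights(1, zero = TRUE)
k <- recurrentKernels(w)
k$li0[2, 2, 1, 1] <- k$li0[2, 2, 2, 2] <- k$li0[2, 2, 3, 3] <- -1
k$ff2[[1]][, , 1, 1] <- 2 / 9; k$ff2[[1]][, , 2, 1] <- 0.6 / 9
k$ff2[[1]][, , 3, 1] <- 0.6 / 9
k$hor[[1]][horizontalMask(1, 1)] <- 2
k$wskip[[2]][] <- 1
w@kernels <- k

gate1 <- list(matrix(0, 36, 36))          # scale-1 gate open on the curve
gate1[[1]][stim@target] <- 0.3
st <- runToFixedPoint(stim, gate1, w, record = TRUE)
st
#> NetworkState: 1 layers, T = 29, converged

## enhancement arrives one cell per step: latency along the curve
lat <- sapply(seq_len(nrow(stim@target)), function(i) {
  tr <- sapply(st@history, function(h) h[[2]][stim@target[i, 1], stim@target[i, 2], 1])
  modulationLatency(tr)
})
head(lat, 10)
#>  [1]  3  2  3  4  5  6  7  8  9 10
```

The latencies grow by one timestep per cell along the curve — the
incremental spread of the attentional label (the cue cell itself is boosted
once more when disinhibition returns from its neighbor at t = 3).  The same
operators drive the scientific analyses: `gapEffect()` measures how a
narrow bottleneck between target and distractor delays enhancement behind
it, `modelRT()` turns the Q-map rise time over the target marker into a
model reaction time for object parsing, and `rtRegression()` /
`r2StandardError()` / `r2DifferenceTest()` quantify how well those RTs
explain (synthetic or real) human reaction times as the number of scales
varies (`scaleAblation()`).

End-to-end training at desk scale:

```r
gw  <- trainGates("curve", nStimuli = 350, epochs = 7)   # scale selection
cfg <- trainerConfig(seed = 1, maxMinutes = 10)
res <- trainCurveTask(gw, cfg, onFailure = "return")     # RELEARNN curriculum
acc <- evaluateNetwork(res$weights, gw,
                       lapply(1:100, function(i) generateCurvePair(36, 7, rngSeed = i)))
```

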