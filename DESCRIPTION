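Package: tracenet
Title: Multiscale Recurrent Networks for Incremental Perceptual Grouping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reinforcement-learning toolkit for a multiscale
    recurrent network model of object-based attention. A feedforward pathway
    selects the spatial scales at which image content is unambiguous and gates
    a recurrent pathway in which VIP/SOM disinhibition spreads enhanced
    activity along a cued curve or over a cued object. The recurrent pathway
    is trained with a local, three-phase reinforcement-learning rule
    (equilibrium forward phase, accessory credit-assignment network, reward
    prediction error) to select an eye-movement target. Includes procedural
    stimulus generators with exact ground truth, supervised training of the
    scale-selection pathway, attentional-modulation latency analyses of
    bottleneck stimuli, model reaction-time estimation for object parsing,
    and regression utilities for comparing model and human reaction times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    png,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'tracenet-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'stimuli.R'
    'gates.R'
    'analysis.R'
    'dynamics.R'
    'decision.R'
    'relearnn.R'
    'training.R'
    'runner.R'
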