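# Finite-difference oracle fixture for the learning rule: a small instance
# whose accessory gradients are compared against central differences.

fdInstance <- function() {
  cached("fdInstance", {
    set.seed(42)
    L <- 2L; H <- 9L
    w <- newRecurrentWeights(nScales = L, seed = 7)
    k <- w@kernels
    k$ff2 <- lapply(k$ff2, function(a) a * 3)   # keep upper layers active
    k$hor <- lapply(k$hor, function(a) a * 0.3) # keep VIP in the linear regime
    k$fb <- lapply(k$fb, function(a) a * 0.4)
    # generic operating point: zero-initialized feedback sits exactly on the
    # clip kink, where the rule prescribes subgradient 0 but a central
    # difference straddles the corner
    k$fb[[1]][] <- runif(length(k$fb[[1]]), 0.05, 0.15)
    w <- methods::initialize(w, kernels = k)
    img <- array(runif(H * H * 3) * (runif(H * H * 3) < 0.4), c(H, H, 3))
    gates <- randomGates(H, L, density = 0.7)
    st <- runToFixedPoint(img, gates, w, tMax = 500, tol = 1e-13)
    q <- computeQMap(st, w, warn = FALSE)
    # act on a pixel whose input-layer unit is active so the input-layer
    # skip gradient is exercised too
    ok <- apply(st@Y[[1]], c(1, 2), max) > 0
    qa <- abs(q); qa[!ok] <- -Inf
    action <- c(row(q)[which.max(qa)], col(q)[which.max(qa)])
    list(w = w, img = img, gates = gates, st = st, action = action, q = q)
  })
}

fdQa <- function(inst, w) {
  st <- runToFixedPoint(inst$img, inst$gates, w, tMax = 500, tol = 1e-13)
  q <- computeQMap(st, w, warn = FALSE)
  q[inst$action[1], inst$action[2]]
}

perturbW <- function(w, fam, l, idx, h) {
  k <- w@kernels
  if (fam == "li0") k[[fam]][idx] <- k[[fam]][idx] + h
  else k[[fam]][[l]][idx] <- k[[fam]][[l]][idx] + h
  methods::initialize(w, kernels = k)
}

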