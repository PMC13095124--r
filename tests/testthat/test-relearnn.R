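# Finite-difference oracle for the learning rule: beta-normalized updates
# must equal dQa/dw for every kernel family (the Almeida-Pineda equivalence).

test_that("accessory credit times pre-synaptic activity equals dQa/dw", {
  inst <- fdInstance()
  expect_true(isConverged(inst$st))
  acc <- accessoryPropagate(inst$st, inst$img, inst$gates, inst$w,
                            inst$action, tMax = 500, tol = 1e-13)
  expect_true(acc$converged)
  h <- 1e-6
  set.seed(1)
  for (fam in c("ff2", "fb", "hor", "li0", "wskip")) {
    gf <- acc$grads[[fam]]
    lset <- if (fam == "li0") 1L else seq_along(gf)
    checkedNonzero <- FALSE
    for (l in lset) {
      g <- if (fam == "li0") gf else gf[[l]]
      valid <- seq_along(g)
      if (fam == "hor") valid <- which(horizontalMask(dim(g)[3], dim(g)[4]))
      if (fam == "li0") {
        m <- array(FALSE, dim(g)); m[2, 2, , ] <- TRUE; valid <- which(m)
      }
      nz <- intersect(which(abs(g) > 1e-4), valid)
      pick <- if (length(nz)) sample(nz, min(4L, length(nz))) else integer()
      pick <- union(pick, sample(valid, min(2L, length(valid))))
      for (idx in pick) {
        qp <- fdQa(inst, perturbW(inst$w, fam, l, idx, h))
        qm <- fdQa(inst, perturbW(inst$w, fam, l, idx, -h))
        fd <- (qp - qm) / (2 * h)
        an <- g[idx]
        if (max(abs(fd), abs(an)) > 1e-4) {
          expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
          checkedNonzero <- TRUE
        } else {
          expect_lt(abs(fd - an), 1e-6)
        }
      }
    }
    expect_true(checkedNonzero, label = paste("nonzero gradient checked for", fam))
  }
})

test_that("credit is zero for units on the ReLU floor", {
  inst <- fdInstance()
  acc <- accessoryPropagate(inst$st, inst$img, inst$gates, inst$w,
                            inst$action, tMax = 500, tol = 1e-13)
  for (l in seq_along(acc$creditPyr)) {
    dead <- inst$st@Y[[l]] == 0
    expect_true(all(acc$creditPyr[[l]][dead] == 0))
  }
})

test_that("skip gradients are exactly the pre-synaptic activity at the action", {
  inst <- fdInstance()
  acc <- accessoryPropagate(inst$st, inst$img, inst$gates, inst$w,
                            inst$action, tMax = 200, tol = 1e-12)
  a <- inst$action
  expect_equal(as.vector(acc$grads$wskip[[1]]),
               as.vector(inst$st@Y[[1]][a[1], a[2], ]))
  # layer-l skip gradient is nonzero only at the footprint position
  for (l in 1:2) {
    K <- 3^l
    g <- acc$grads$wskip[[l + 1]]
    fi <- (a[1] - 1) %/% K + 1; fj <- (a[2] - 1) %/% K + 1
    u <- a[1] - (fi - 1) * K; v <- a[2] - (fj - 1) * K
    expect_equal(as.vector(g[u, v, ]), as.vector(inst$st@Y[[l + 1]][fi, fj, ]))
    g[u, v, ] <- 0
    expect_true(all(g == 0))
  }
})

test_that("a zero prediction error leaves the weights bit-identical", {
  inst <- fdInstance()
  acc <- accessoryPropagate(inst$st, inst$img, inst$gates, inst$w,
                            inst$action)
  w2 <- applyUpdate(inst$w, acc$grads, delta = 0, beta = 0.1)
  expect_identical(w2@kernels, inst$w@kernels)
})

test_that("the update is the product beta * delta * pre * credit", {
  w <- newRecurrentWeights(1L, zero = TRUE)
  grads <- list(ff2 = list(array(0, c(3, 3, 3, 1))),
                fb = list(array(0, c(3, 3, 1, 3))),
                hor = list(array(0, c(3, 3, 1, 1))),
                li0 = array(0, c(3, 3, 3, 3)),
                wskip = list(array(0, c(1, 1, 3)), array(0, c(3, 3, 1))))
  grads$ff2[[1]][1, 1, 1, 1] <- 1 * 0.5  # pre-activity 1, credit 0.5
  w2 <- applyUpdate(w, grads, delta = 0.2, beta = 0.1)
  expect_equal(w2@kernels$ff2[[1]][1, 1, 1, 1], 0.01)
  expect_true(all(w2@kernels$ff2[[1]][-1] == 0))
  # masks survive updates even when the raw gradient violates them
  grads$hor[[1]][2, 2, 1, 1] <- 1
  w3 <- applyUpdate(w, grads, delta = 1, beta = 1)
  expect_equal(w3@kernels$hor[[1]][2, 2, 1, 1], 0)
})

test_that("repeated rewarded updates drive Qa monotonically toward 1", {
  set.seed(5)
  w <- newRecurrentWeights(1L, seed = 9)
  img <- array(runif(9 * 9 * 3) * (runif(9 * 9 * 3) < 0.5), c(9, 9, 3))
  gates <- randomGates(9, 1, density = 0.9)
  st <- runToFixedPoint(img, gates, w, tMax = 200, tol = 1e-10)
  q <- computeQMap(st, w, warn = FALSE)
  action <- c(row(q)[which.max(q)], col(q)[which.max(q)])
  qas <- numeric(40)
  for (i in seq_along(qas)) {
    st <- runToFixedPoint(img, gates, w, tMax = 200, tol = 1e-10)
    q <- computeQMap(st, w, warn = FALSE)
    qas[i] <- q[action[1], action[2]]
    acc <- accessoryPropagate(st, img, gates, w, action, tMax = 200,
                              tol = 1e-10)
    w <- applyUpdate(w, acc$grads, delta = 1 - qas[i], beta = 0.05)
  }
  expect_true(all(diff(qas) > -1e-8))
  expect_gt(qas[40], qas[1])
  expect_gt(qas[40], 0.5)
})

test_that("identical seeds reproduce an identical training trajectory", {
  gw <- newGateWeights(2, seed = 1)  # untrained gates suffice for determinism
  run <- function() {
    set.seed(123)
    w <- newRecurrentWeights(2, seed = 11)
    cfg <- trainerConfig(beta = 0.01, epsilon = 0.2, seed = 123)
    pool <- tracenet:::makePool(5, function() generateCurvePair(9, 3), gw, 2L)
    for (i in 1:25) {
      e <- pool[[sample.int(5, 1)]]
      w <- tracenet:::poolTrial(e, w, cfg, cfg@epsilon, learn = TRUE)$weights
    }
    w@kernels
  }
  expect_identical(run(), run())
})
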