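# Synthetic session generator: geometry, determinism, outliers, user model.

test_that("prototypes sit at the configured geodesic geometry", {
  cfg <- generatorConfig(nChannels = 8L, separation = 0.3, seed = 5L)
  pr <- makePrototypes(cfg)
  expect_true(all(vapply(pr$prototypes, isSPD, logical(1))))
  # orthonormal directions: pairwise distances close to delta * sqrt(2)
  for (a in 1:3) for (b in (a + 1):4) {
    expect_equal(riemannDistance(pr$prototypes[[a]], pr$prototypes[[b]]),
                 0.3 * sqrt(2), tolerance = 0.01)
  }
  expect_equal(riemannDistance(pr$prototypes[[1]], pr$base), 0.3,
               tolerance = 1e-6)
  # zero separation collapses everything onto the base
  pr0 <- makePrototypes(generatorConfig(nChannels = 8L, separation = 0,
                                        seed = 5L))
  expect_equal(pr0$prototypes[[1]], pr0$base, tolerance = 1e-10)
  # determinism
  pr2 <- makePrototypes(cfg)
  expect_identical(pr$prototypes, pr2$prototypes)
})

test_that("trial covariances converge to the prototype and replays are
           bit-identical", {
  cfg <- generatorConfig(nChannels = 8L, separation = 0.3, seed = 5L)
  pr <- makePrototypes(cfg)
  tr <- generateTrial(pr$prototypes[[1]], tau = 0, pOut = 0, seed = 3L,
                      nSamples = 1e5, rate = 64)
  expect_lt(riemannDistance(covDescriptor(tr$samples),
                            pr$prototypes[[1]]), 0.1)
  tr2 <- generateTrial(pr$prototypes[[1]], tau = 0, pOut = 0, seed = 3L,
                       nSamples = 1e5, rate = 64)
  expect_identical(tr$samples, tr2$samples)
})

test_that("sessions are deterministic with balanced per-run labels", {
  cfg <- generatorConfig(nChannels = 6L, rate = 64, nRuns = 2L,
                         trialsPerClass = 5L, seed = 17L)
  s1 <- generateSession(cfg)
  s2 <- generateSession(cfg)
  expect_identical(trialData(s1), trialData(s2))
  expect_identical(trialInfo(s1), trialInfo(s2))
  info <- trialInfo(s1)
  for (r in unique(info$run)) {
    expect_equal(as.numeric(table(info$label[info$run == r])), rep(5, 4))
  }
})

test_that("implanted outliers are the farthest segments from the trial
           mean", {
  s <- generateSession(generatorConfig(nChannels = 8L, rate = 64,
                                       nRuns = 1L, trialsPerClass = 3L,
                                       separation = 0.5, tau = 0.2,
                                       pOut = 1, seed = 11L))
  fl <- outlierFlags(s, 0)
  rc <- runCovariances(s, 0)
  hits <- vapply(seq_len(nrow(fl)), function(tr) {
    idx <- which(rc$info$trial == tr)
    mu <- karcherMean(rc$covs[idx])
    dd <- vapply(rc$covs[idx], riemannDistance, numeric(1), S2 = mu)
    fl[tr, which.max(dd)]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("drift-free unit-gamma runs are statistically exchangeable", {
  cfg <- generatorConfig(nChannels = 6L, rate = 64, nRuns = 2L,
                         trialsPerClass = 5L, separation = 0.8, tau = 0.3,
                         drift = 0, gamma = 1, pOut = 0, seed = 23L)
  s <- generateSession(cfg)
  sepRun <- function(run) {
    rc <- runCovariances(s, run)
    byClass <- lapply(1:2, function(c) rc$covs[rc$info$label == c])
    classSeparability(byClass[[1]], byClass[[2]])
  }
  s0 <- sepRun(0); s1 <- sepRun(1)
  expect_lt(abs(s0 - s1) / max(s0, s1), 0.35)
})

test_that("class prototypes are recoverable from a generated run", {
  cfg <- generatorConfig(nChannels = 8L, rate = 64, nRuns = 1L,
                         trialsPerClass = 10L, separation = 0.8,
                         tau = 0.15, drift = 0, gamma = 1, pOut = 0,
                         seed = 29L)
  s <- generateSession(cfg)
  rc <- runCovariances(s, 0)
  gt <- groundTruth(s)
  for (c in 1:4) {
    est <- karcherMean(rc$covs[rc$info$label == c])
    expect_lt(riemannDistance(est, gt$prototypes[[1]][[c]]), 0.2)
  }
})

test_that("the user model contracts, inflates and drifts as specified", {
  cfg <- generatorConfig(nChannels = 4L, seed = 3L)
  pr <- makePrototypes(cfg)
  set.seed(3)
  state <- list(tau = 0.4, gamma = 0.9, prototypes = pr$prototypes,
                driftDirs = lapply(1:4, function(i) {
                  riemix:::.randomUnitTangent(4)
                }),
                driftStep = 0.2)
  s3 <- state
  for (i in 1:3) s3 <- userModelStep(s3, "trial_correct")
  expect_equal(s3$tau, 0.4 * 0.9^3)
  alt <- state
  for (i in 1:2) {
    alt <- userModelStep(alt, "trial_correct")
    alt <- userModelStep(alt, "trial_incorrect")
  }
  expect_equal(alt$tau, state$tau)
  moved <- userModelStep(state, "regime_change")
  for (c in 1:4) {
    expect_equal(riemannDistance(moved$prototypes[[c]],
                                 state$prototypes[[c]]), 0.2,
                 tolerance = 1e-6)
  }
})
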