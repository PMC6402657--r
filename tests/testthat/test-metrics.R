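# Evaluation metrics: confusion quality, separability, instability,
# signed-rank tests, regression over runs.

test_that("confusion quality rewards balance, not raw accuracy", {
  Q <- matrix(0.125, 4, 4); diag(Q) <- 0.5; Q <- Q / rowSums(Q)
  expect_equal(confusionQuality(Q), 1)
  # constant one-class predictor: 25% accuracy but zero quality
  truth <- rep(1:4, each = 10)
  pred <- rep(1L, 40)
  Qc <- confusionMatrix(truth, pred)
  expect_equal(mean(pred == truth), 0.25)
  expect_equal(confusionQuality(Qc), 0)
  Qd <- diag(c(0.8, 0.6, 0.4, 0.2))
  expect_equal(confusionQuality(Qd), 0.2 / 0.5)
  # invariant to joint permutation of classes
  p <- c(3, 1, 4, 2)
  expect_equal(confusionQuality(Qd[p, p]), confusionQuality(Qd))
  expect_lte(confusionQuality(matrix(runif(16), 4)), 1)
})

test_that("row-normalized confusion matrix has unit rows", {
  set.seed(1)
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- sample(1:4, 200, replace = TRUE)
  Q <- confusionMatrix(truth, pred)
  expect_equal(rowSums(Q), rep(1, 4))
  Qn <- confusionMatrix(truth, pred, counts = TRUE)
  expect_equal(sum(Qn), 200)
})

test_that("separability is symmetric, zero for identical classes, and
           recovers constructed geometry", {
  set.seed(12)
  covs <- lapply(1:20, function(i) randSPD(4))
  expect_equal(classSeparability(covs, covs), 0)
  covsB <- lapply(1:20, function(i) randSPD(4))
  expect_equal(classSeparability(covs, covsB),
               classSeparability(covsB, covs), tolerance = 1e-8)
  expect_error(classSeparability(rep(list(diag(3)), 5),
                                 rep(list(diag(3)), 5)), "degenerate")

  # parameter recovery: classes implanted at geodesic distance delta with
  # isotropic tangent noise of per-axis sd s; sd of member distances
  # concentrates near s/sqrt(2) in high dimension, so separability is
  # approximately 2 * delta / s^2
  d <- 8; q <- d * (d + 1) / 2
  s <- 0.05; delta <- 0.6
  U <- unvecSym(c(1, rep(0, q - 1)), d)   # unit direction
  mkClass <- function(center) {
    lapply(1:330, function(i) {
      expMap(unvecSym(rnorm(q, sd = s), d), center)
    })
  }
  A <- mkClass(expMap(+delta / 2 * U, diag(d)))
  B <- mkClass(expMap(-delta / 2 * U, diag(d)))
  sep <- classSeparability(A, B)
  predicted <- 2 * delta / s^2
  expect_lt(abs(sep - predicted) / predicted, 0.15)
})

test_that("instability counts the components holding 95% of tangent
           variance", {
  set.seed(4)
  # variance confined to an exact 3-dim tangent subspace
  B <- lapply(1:3, function(i) { M <- matrix(0, 6, 6); M[i, i] <- 1; M })
  covs3 <- lapply(1:200, function(i) {
    z <- rnorm(3)
    expMap(0.3 * (z[1] * B[[1]] + z[2] * B[[2]] + z[3] * B[[3]]), diag(6))
  })
  expect_equal(classInstability(covs3), 3L)
  # identical covariances: zero variance
  expect_equal(classInstability(rep(list(2 * diag(4)), 5)), 0L)
  # isotropic noise in all q = 78 dimensions needs nearly all components
  d <- 12; q <- d * (d + 1) / 2
  covs <- lapply(1:330, function(i) {
    expMap(unvecSym(rnorm(q, sd = 0.3), d), diag(d))
  })
  inst <- classInstability(covs)
  expect_gte(inst, ceiling(0.85 * q))
  expect_lte(inst, q)
})

test_that("exact signed-rank p-values match closed forms and enumeration", {
  expect_equal(wilcoxonLeftExact(1:8, 2:9), 1 / 256)
  expect_equal(wilcoxonLeftExact(1:6, (1:6) + 0.5), 1 / 64)
  expect_error(wilcoxonLeftExact(1:4, 1:4), "zero")
  expect_error(wilcoxonLeftExact(1:3, 1:4), "length")
  # full-enumeration oracle, including ties and zero differences
  set.seed(6)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    before <- round(rnorm(n), 1)
    after <- before + round(rnorm(n), 1)
    if (all(before == after)) next
    expect_equal(wilcoxonLeftExact(before, after),
                 wilcoxonLeftEnum(before, after))
  }
})

test_that("regression over runs matches least squares", {
  expect_equal(regressOverRuns(rep(3, 4)), c(a = 0, b = 3))
  expect_equal(regressOverRuns(2 * (1:4) + 1), c(a = 2, b = 1))
  r <- regressOverRuns(c(29.6, 39.0, 41.3, 41.4))
  expect_equal(unname(round(r, 2)), c(3.77, 28.40))
})

test_that("kappa-accuracy conversion and table rounding conventions", {
  expect_equal(kappaToAccuracy(0.4), 0.55)
  expect_equal(kappaToAccuracy(0), 0.25)
  expect_equal(tableRound(c(0.0039, 0.1562), "p"), c(0.004, 0.16))
  expect_equal(tableRound(29.94, "score"), 29.9)
})
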