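# Geometry of SPD covariance descriptors: distances, maps, Karcher mean.

test_that("covariance descriptor recovers known covariances", {
  # two orthogonal rows of squared norm T-1 give the identity
  T <- 101
  X <- rbind(c(rep(1, 50), rep(-1, 50), 0), c(rep(1, 25), rep(-1, 50),
                                              rep(1, 25), 0))
  X <- X * sqrt((T - 1) / rowSums(X^2))
  expect_equal(covDescriptor(X), diag(2), tolerance = 1e-12)

  # duplicated rows are rank deficient
  Xdup <- matrix(rnorm(100), 1)[c(1, 1), ]
  expect_error(covDescriptor(Xdup), "degenerate")
  expect_true(isSPD(covDescriptor(Xdup, shrinkage = 1e-4)))

  # Monte-Carlo convergence to the target covariance
  set.seed(5)
  S <- randSPD(6)
  A <- t(chol(S))
  X <- A %*% matrix(rnorm(6 * 1e5), 6)
  C <- covDescriptor(X)
  expect_lt(norm(C - S, "F"), 0.05 * norm(S, "F"))
})

test_that("Riemannian distance matches closed forms and is a metric", {
  A <- randSPD(4)
  expect_equal(riemannDistance(A, A), 0, tolerance = 1e-8)
  expect_equal(riemannDistance(diag(2), diag(c(exp(2), 1))), 2,
               tolerance = 1e-10)
  expect_equal(riemannDistance(diag(2), diag(c(4, 4))), sqrt(2) * log(4),
               tolerance = 1e-10)
  B <- randSPD(4)
  expect_equal(riemannDistance(A, B), riemannDistance(B, A),
               tolerance = 1e-10)
  expect_error(riemannDistance(diag(2), diag(3)), "dimension")
  expect_error(riemannDistance(matrix(c(1, 2, 0, 1), 2), diag(2)),
               "positive definite")
})

test_that("distance is invariant to affine congruence and inversion", {
  set.seed(11)
  for (i in 1:10) {
    S1 <- randSPD(4); S2 <- randSPD(4)
    M <- matrix(rnorm(16), 4)
    d0 <- riemannDistance(S1, S2)
    expect_equal(riemannDistance(M %*% S1 %*% t(M), M %*% S2 %*% t(M)), d0,
                 tolerance = 1e-8)
    expect_equal(riemannDistance(solve(S1), solve(S2)), d0,
                 tolerance = 1e-8)
  }
})

test_that("log and exp maps are mutually inverse", {
  C <- randSPD(3)
  expect_equal(logMap(C, C)@mat, matrix(0, 3, 3), tolerance = 1e-10)
  expect_equal(logMap(diag(c(exp(2), 1)), diag(2))@mat, diag(c(2, 0)),
               tolerance = 1e-10)
  expect_equal(expMap(matrix(0, 3, 3), C), C, tolerance = 1e-10)
  expect_equal(expMap(diag(c(2, 0)), diag(2)), diag(c(exp(2), 1)),
               tolerance = 1e-10)
  set.seed(2)
  worst <- 0
  for (i in 1:100) {
    S <- randSPD(4); Cr <- randSPD(4)
    back <- expMap(logMap(S, Cr))
    worst <- max(worst, max(abs(back - S)))
  }
  expect_lt(worst, 1e-8)
})

test_that("tangent vectorization is an isometry", {
  expect_length(tangentVectorize(matrix(0, 12, 12)), 78)
  expect_equal(tangentVectorize(matrix(0, 5, 5)), rep(0, 15))
  set.seed(3)
  worst <- 0
  for (i in 1:100) {
    M <- matrix(rnorm(36), 6); M <- (M + t(M)) / 2
    worst <- max(worst, abs(sqrt(sum(tangentVectorize(M)^2)) -
                              norm(M, "F")))
  }
  expect_lt(worst, 1e-12)
})

test_that("tangent distance approximates the Riemannian distance", {
  S <- randSPD(4); C <- randSPD(4)
  expect_equal(tangentDistance(S, S, C), 0, tolerance = 1e-10)
  # exact for commuting diagonal matrices with identity reference
  D1 <- diag(c(1, 2, 5)); D2 <- diag(c(3, 1, 0.5))
  expect_equal(tangentDistance(D1, D2, diag(3)), riemannDistance(D1, D2),
               tolerance = 1e-10)
  # local approximation: relative error below 1% for nearby pairs
  set.seed(7)
  for (i in 1:20) {
    Cr <- randSPD(4)
    T1 <- unvecSym(rnorm(10, sd = 0.01), 4)
    T2 <- unvecSym(rnorm(10, sd = 0.01), 4)
    S1 <- expMap(T1, Cr); S2 <- expMap(T2, Cr)
    dR <- riemannDistance(S1, S2)
    dT <- tangentDistance(S1, S2, Cr)
    expect_lt(abs(dT - dR) / dR, 0.01)
  }
})

test_that("Karcher mean handles degenerate and commuting cases", {
  A <- randSPD(3)
  expect_equal(karcherMean(list(A)), A, tolerance = 1e-10)
  expect_equal(karcherMean(list(A, A, A)), A, tolerance = 1e-6)
  # geometric mean of commuting matrices
  expect_equal(karcherMean(list(diag(c(1, 4)), diag(c(4, 1)))),
               diag(c(2, 2)), tolerance = 1e-6)
  # permutation invariance
  set.seed(8)
  covs <- lapply(1:5, function(i) randSPD(3))
  m1 <- karcherMean(covs)
  m2 <- karcherMean(rev(covs))
  expect_equal(m1, m2, tolerance = 1e-6)
  # zero mean tangent vector at the solution
  Tbar <- Reduce(`+`, lapply(covs, function(S) logMap(S, m1)@mat)) / 5
  expect_lt(norm(Tbar, "F"), 1e-5)
  expect_error(karcherMean(list()), "empty")
  expect_error(karcherMean(covs, maxIter = 1L), "converge")
})

test_that("Karcher mean agrees with an independent minimizer", {
  set.seed(21)
  for (rep in 1:3) {
    covs <- lapply(1:(2 + rep), function(i) randSPD(3))
    km <- karcherMean(covs, tol = 1e-10)
    oracle <- karcherOracle(covs)
    expect_lt(riemannDistance(km, oracle), 1e-5)
  }
})

test_that("Karcher mean is equivariant under congruence", {
  set.seed(9)
  covs <- lapply(1:4, function(i) randSPD(3))
  M <- matrix(rnorm(9), 3)
  m1 <- karcherMean(lapply(covs, function(S) M %*% S %*% t(M)), tol = 1e-10)
  m2 <- M %*% karcherMean(covs, tol = 1e-10) %*% t(M)
  expect_equal(m1, m2, tolerance = 1e-6)
})
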