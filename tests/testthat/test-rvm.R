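# Multinomial-probit RVM: kernel, sparsity, calibration, invariances.

test_that("the Gaussian kernel follows its closed form", {
  x <- c(1, 2, 3)
  expect_equal(rbfKernel(x, x, 2), 1)
  expect_equal(rbfKernel(c(0, 0), c(2, 0), sigma = sqrt(2)), exp(-1))
  d <- seq(0.5, 5, by = 0.5)
  k <- vapply(d, function(dd) rbfKernel(0, dd, 1), numeric(1))
  expect_true(all(diff(k) < 0))
  expect_error(rbfKernel(x, x, 0), "positive")
  expect_error(rbfKernel(x, c(1, 2), 1), "mismatch")
})

test_that("well-separated blobs are learned exactly and sparsely", {
  b <- blobData(n = 40, sep = 10, sd = 1)
  m <- trainRVM(b$X, b$y)
  pred <- predictClass(m, b$X)
  # brute-force nearest-centroid oracle
  cents <- do.call(rbind, lapply(1:4, function(c) colMeans(b$X[b$y == c, ])))
  oracle <- apply(b$X, 1, function(x) {
    which.min(colSums((t(cents) - x)^2))
  })
  expect_equal(pred, oracle)
  expect_equal(mean(pred == b$y), 1)
  expect_lt(nrow(m@relVectors), nrow(b$X))
  # a relevance vector of an easy problem is confidently its own class
  P <- predictProba(m, b$X)
  expect_gt(P[m@relIndex[1], b$y[m@relIndex[1]]], 0.9)
})

test_that("probabilities are a proper distribution with deterministic
           tie-breaking", {
  b <- blobData(n = 24, sep = 6)
  m <- trainRVM(b$X, b$y)
  set.seed(30)
  Xt <- matrix(rnorm(2000, sd = 5), ncol = 2)
  P <- predictProba(m, Xt)
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_error(predictProba(m, matrix(0, 1, 5)), "length mismatch")
})

test_that("label-shuffled training yields chance-level probabilities", {
  b <- blobData(n = 40, sep = 10)
  set.seed(31)
  ys <- sample(b$y)
  m <- trainRVM(b$X, ys)
  P <- predictProba(m, b$X)
  expect_true(all(abs(colMeans(P) - 0.25) < 0.15))
})

test_that("duplicating the training set leaves decisions unchanged", {
  b <- blobData(n = 40, sep = 10)
  m1 <- trainRVM(b$X, b$y)
  m2 <- trainRVM(rbind(b$X, b$X), c(b$y, b$y), sigma = m1@sigma)
  set.seed(32)
  Xt <- b$X + matrix(rnorm(80, sd = 0.5), ncol = 2)
  P1 <- predictProba(m1, Xt); P2 <- predictProba(m2, Xt)
  expect_equal(apply(P1, 1, which.max), apply(P2, 1, which.max))
  expect_lt(mean(abs(P1 - P2)), 0.05)
})

test_that("predictions are invariant to rigid transforms of the feature
           space", {
  b <- blobData(n = 32, sep = 8)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  shift <- c(3, -5)
  Xr <- sweep(b$X %*% R, 2, shift, "+")
  m1 <- trainRVM(b$X, b$y)
  m2 <- trainRVM(Xr, b$y)
  expect_equal(m1@sigma, m2@sigma, tolerance = 1e-10)
  set.seed(33)
  Xt <- matrix(rnorm(60, sd = 4), ncol = 2)
  Xtr <- sweep(Xt %*% R, 2, shift, "+")
  expect_equal(predictProba(m1, Xt), predictProba(m2, Xtr),
               tolerance = 1e-6)
})

test_that("accuracy keeps up with a margin oracle on separable toys", {
  set.seed(34)
  b <- blobData(n = 80, sep = 5, sd = 1, seed = 34)
  btest <- blobData(n = 80, sep = 5, sd = 1, seed = 35)
  m <- trainRVM(b$X, b$y)
  acc <- mean(predictClass(m, btest$X) == btest$y)
  cents <- do.call(rbind, lapply(1:4, function(c) colMeans(b$X[b$y == c, ])))
  accOracle <- mean(apply(btest$X, 1, function(x) {
    which.min(colSums((t(cents) - x)^2))
  }) == btest$y)
  expect_gte(acc, accOracle - 0.05)
})

test_that("degenerate training inputs are rejected", {
  b <- blobData(n = 16, sep = 5)
  expect_error(trainRVM(b$X, rep(1L, 16)), "2 classes")
  Xbad <- b$X; Xbad[1, 1] <- NA
  expect_error(trainRVM(Xbad, b$y), "non-finite")
})
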