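# Shared fixtures, memoized so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# random SPD matrix
randSPD <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + scale * diag(d)
}

# symmetric matrix from a vectorized isometric representation
unvecSym <- function(v, d) {
  M <- diag(v[1:d], d)
  M[upper.tri(M)] <- v[(d + 1):length(v)] / sqrt(2)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

# four Gaussian blobs in 2-D, separation `sep` between centers
blobData <- function(n = 40, sep = 10, sd = 1, seed = 42) {
  set.seed(seed)
  cents <- rbind(c(0, 0), c(sep, 0), c(0, sep), c(sep, sep))
  X <- do.call(rbind, lapply(1:4, function(c) {
    sweep(matrix(rnorm(n / 4 * 2, sd = sd), ncol = 2), 2, cents[c, ], "+")
  }))
  list(X = X, y = rep(1:4, each = n / 4))
}

# small high-separation synthetic session (8 ch, 64 Hz, 3 runs)
smallSession <- function() {
  memo("smallSession", generateSession(generatorConfig(
    nChannels = 8L, rate = 64, nRuns = 3L, trialsPerClass = 5L,
    separation = 1.2, tau = 0.2, drift = 0, gamma = 1, pOut = 0,
    seed = 71L)))
}

# adapted mixture over the small session (2 runs of adaptation)
smallAdapt <- function() {
  memo("smallAdapt", {
    suppressWarnings(adaptSession(smallSession(), kRange = 8:10, d = 4L,
                                  maxRuns = 2))
  })
}

smallRC <- function(run) {
  memo(paste0("smallRC", run), runCovariances(smallSession(), run))
}

# independent Fréchet-mean minimizer: BFGS over the Cholesky factor with the
# sum of squared Riemannian distances as objective
karcherOracle <- function(covs) {
  d <- nrow(covs[[1]])
  toMat <- function(theta) {
    L <- diag(exp(theta[1:d]), d)
    L[lower.tri(L)] <- theta[-(1:d)]
    tcrossprod(L)
  }
  obj <- function(theta) {
    M <- toMat(theta)
    sum(vapply(covs, function(S) riemannDistance(S, M)^2, numeric(1)))
  }
  A <- Reduce(`+`, covs) / length(covs)
  L0 <- t(chol(A))
  init <- c(log(diag(L0)), L0[lower.tri(L0)])
  opt <- stats::optim(init, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  toMat(opt$par)
}
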