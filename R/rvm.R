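# Sparse multinomial-probit relevance vector machine (pruning flavour):
# Gaussian kernel on tangent-space features, MAP weight updates with
# per-sample precision hyper-parameters, truncated-Gaussian latent
# expectations computed by fixed-node Gauss-Hermite quadrature, pruning by
# hyper-parameter divergence.

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix),
# transformed so that E_{u ~ N(0,1)}[g(u)] = sum(w * g(x)).
.gaussHermiteNormal <- function(n) {
  if (n == 1) return(list(x = 0, w = 1))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  # physicists' nodes/weights; eigenvalues ascending after reordering
  ord <- order(e$values)
  x <- e$values[ord]
  w <- e$vectors[1, ord]^2   # weights sum to 1 after this normalization
  list(x = sqrt(2) * x, w = w)
}

#' Gaussian kernel on feature vectors
#'
#' `exp(-||x - y||^2 / (2 sigma^2))`; the kernel applied to tangent-space
#' features, so it depends on the data only through tangent distances.
#'
#' @param x,y numeric vectors of equal length
#' @param sigma bandwidth (> 0)
#' @return scalar in (0, 1]
#' @export
rbfKernel <- function(x, y, sigma) {
  if (length(x) != length(y)) stop("feature length mismatch")
  if (sigma <= 0) stop("sigma must be positive")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

# pairwise kernel matrix between row-feature matrices
.kernelMatrix <- function(A, B, sigma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Median-heuristic kernel bandwidth
#'
#' Median pairwise Euclidean distance of the training features; the
#' bandwidth recorded in every trained model.
#'
#' @param features n x p feature matrix
#' @return positive scalar
#' @export
medianBandwidth <- function(features) {
  d <- stats::dist(features)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

# Truncated-Gaussian latent expectations for the multinomial probit.
# F: n x C matrix of regressions, labels: true class per row.
# Returns the expected latent matrix Y (n x C), vectorized over samples
# with one pass per quadrature node and class.
.probitLatent <- function(F, labels, quad) {
  n <- nrow(F); C <- ncol(F)
  idxTrue <- cbind(seq_len(n), labels)
  delta <- F[idxTrue] - F              # n x C, delta_j = f_i - f_j
  nq <- length(quad$x)
  # Phi(u_k + delta) per node, true-class column set to 1 so row products
  # run over j != i
  Phi <- array(0, c(n, C, nq))
  prodAll <- matrix(0, n, nq)
  for (k in seq_len(nq)) {
    Pk <- stats::pnorm(quad$x[k] + delta)
    Pk[idxTrue] <- 1
    Phi[, , k] <- Pk
    prodAll[, k] <- apply(Pk, 1, prod)
  }
  Z <- pmax(drop(prodAll %*% quad$w), 1e-12)
  Y <- F
  shift <- numeric(n)
  for (c in seq_len(C)) {
    num <- numeric(n)
    for (k in seq_len(nq)) {
      phi_c <- stats::dnorm(quad$x[k] + delta[, c])
      num <- num + quad$w[k] * phi_c * prodAll[, k] /
        pmax(Phi[, c, k], 1e-300)
    }
    corr <- num / Z
    isTrue <- labels == c
    corr[isTrue] <- 0
    Y[, c] <- F[, c] - corr
    shift <- shift + corr
  }
  Y[idxTrue] <- F[idxTrue] + shift
  Y
}

#' Train a multi-class relevance vector machine
#'
#' Multinomial-probit RVM with a Gaussian kernel, trained on the full kernel
#' and sparsified by pruning: per-sample precision hyper-parameters alpha
#' receive MacKay/EM updates, samples whose alpha diverges beyond
#' `pruneThreshold` are removed from the basis, and training stops when the
#' surviving log-alphas change by less than `tol` (or after `maxIter`
#' iterations). Latent truncated-Gaussian expectations are computed by
#' fixed-node Gauss-Hermite quadrature, so training is deterministic given
#' the data.
#'
#' @param features n x p matrix of (tangent-space) features, all finite
#' @param labels integer class labels 1..nClasses, >= 2 samples per class
#' @param sigma Gaussian kernel bandwidth; default the median heuristic
#'   ([medianBandwidth()])
#' @param nClasses number of classes (default: largest label)
#' @param maxIter maximum training iterations
#' @param tol convergence tolerance on log hyper-parameters
#' @param pruneThreshold alpha above which a sample is pruned from the basis
#' @param nQuad quadrature node count
#' @param jitter diagonal jitter added to the kernel matrix
#' @return an [RVMModel-class]
#' @export
trainRVM <- function(features, labels, sigma = NULL, nClasses = NULL,
                     maxIter = 500L, tol = 1e-4, pruneThreshold = 1e5,
                     nQuad = 32L, jitter = 1e-8) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (!all(is.finite(features))) stop("non-finite features")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 classes in the training set")
  if (is.null(nClasses)) nClasses <- max(labels)
  tab <- table(factor(labels, levels = seq_len(nClasses)))
  if (any(tab < 2)) {
    stop("every class needs >= 2 training samples; missing: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  n <- nrow(features)
  if (is.null(sigma)) sigma <- medianBandwidth(features)
  K <- .kernelMatrix(features, features, sigma) + jitter * diag(n)
  KtK <- crossprod(K)
  quad <- .gaussHermiteNormal(nQuad)
  active <- seq_len(n)
  alpha <- rep(1, n)
  C <- nClasses
  W <- matrix(0, n, C)
  for (it in seq_len(maxIter)) {
    Ka <- K[, active, drop = FALSE]
    F <- Ka %*% W[active, , drop = FALSE]
    Y <- .probitLatent(F, labels, quad)
    G <- KtK[active, active, drop = FALSE] + diag(alpha[active],
                                                  length(active))
    Sigma <- tryCatch(chol2inv(chol(G)), error = function(e) {
      stop("kernel system numerically singular after jitter: ",
           conditionMessage(e))
    })
    Wa <- Sigma %*% crossprod(Ka, Y)
    W[active, ] <- Wa
    # MacKay update with shared per-sample precision across classes:
    # gamma_n = 1 - alpha_n Sigma_nn is the well-determinedness of w_n.
    gam <- pmin(pmax(1 - alpha[active] * diag(Sigma), 1e-12), 1)
    alphaNew <- pmin(C * gam / pmax(rowSums(Wa^2), 1e-300), 1e12)
    drift <- max(abs(log(alphaNew) - log(alpha[active])))
    alpha[active] <- alphaNew
    keep <- alphaNew < pruneThreshold
    if (!any(keep)) keep <- alphaNew == min(alphaNew)
    pruned <- !all(keep)
    if (pruned) {
      W[active[!keep], ] <- 0
      active <- active[keep]
    }
    if (!pruned && drift < tol) break
  }
  new("RVMModel",
      relVectors = features[active, , drop = FALSE],
      weights = W[active, , drop = FALSE],
      sigma = sigma, nClasses = as.integer(C), relIndex = as.integer(active))
}

#' Class-membership probabilities from a trained RVM
#'
#' Multinomial-probit probabilities `P(c | x) = E_u[prod_{j != c}
#' Phi(u + f_c - f_j)]`, evaluated by the same fixed-node quadrature used in
#' training and renormalized to sum to one. The predicted class is the
#' argmax, ties broken by the lowest class index.
#'
#' @param model an [RVMModel-class]
#' @param features vector (one sample) or n x p matrix of features
#' @param nQuad quadrature node count
#' @return n x nClasses matrix of probabilities (rows sum to 1)
#' @export
predictProba <- function(model, features, nQuad = 32L) {
  stopifnot(is(model, "RVMModel"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != ncol(model@relVectors)) {
    stop("feature length mismatch: expected ", ncol(model@relVectors))
  }
  K <- .kernelMatrix(features, model@relVectors, model@sigma)
  F <- K %*% model@weights
  quad <- .gaussHermiteNormal(nQuad)
  C <- model@nClasses
  n <- nrow(F)
  P <- matrix(0, n, C)
  for (c in seq_len(C)) {
    others <- setdiff(seq_len(C), c)
    for (k in seq_along(quad$x)) {
      prodPhi <- rep(1, n)
      for (j in others) {
        prodPhi <- prodPhi * stats::pnorm(quad$x[k] + F[, c] - F[, j])
      }
      P[, c] <- P[, c] + quad$w[k] * prodPhi
    }
  }
  P / rowSums(P)
}

#' Predicted classes from a trained RVM
#'
#' @inheritParams predictProba
#' @return integer vector of predicted classes (argmax probability, ties to
#'   the lowest class index)
#' @export
predictClass <- function(model, features, nQuad = 32L) {
  P <- predictProba(model, features, nQuad = nQuad)
  apply(P, 1, which.max)
}
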