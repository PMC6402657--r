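# Geometry of symmetric positive-definite (SPD) matrices: covariance
# descriptors, matrix log/exp, affine-invariant Riemannian distance,
# tangent-space maps and the iterative Karcher mean.

.symmetrize <- function(S) (S + t(S)) / 2

# Eigendecomposition of the symmetrized matrix; eigenvalues clipped below at
# `clip` (with a warning) so log/inverse-sqrt stay finite on near-singular
# input.
.eigSym <- function(S, clip = 1e-12, warn = TRUE) {
  e <- eigen(.symmetrize(S), symmetric = TRUE)
  if (any(e$values < clip)) {
    if (warn) warning("eigenvalues clipped at ", clip,
                      " (near-singular SPD input)")
    e$values <- pmax(e$values, clip)
  }
  e
}

.spdFun <- function(S, f, clip = 1e-12, warn = TRUE) {
  e <- .eigSym(S, clip = clip, warn = warn)
  .symmetrize(e$vectors %*% (f(e$values) * t(e$vectors)))
}

.matLog <- function(S, warn = TRUE) .spdFun(S, log, warn = warn)
.matExp <- function(S) {
  e <- eigen(.symmetrize(S), symmetric = TRUE)
  .symmetrize(e$vectors %*% (exp(e$values) * t(e$vectors)))
}
.matPow <- function(S, p, warn = TRUE) .spdFun(S, function(l) l^p, warn = warn)

#' Test a matrix for symmetric positive definiteness
#'
#' @param S a square numeric matrix
#' @param tol relative symmetry tolerance and eigenvalue floor
#' @return logical
#' @export
isSPD <- function(S, tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S) || !all(is.finite(S))) return(FALSE)
  if (max(abs(S - t(S))) > tol * (1 + max(abs(S)))) return(FALSE)
  ev <- eigen(.symmetrize(S), symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0)
}

.assertSPD <- function(S, name = deparse(substitute(S))) {
  if (!isSPD(S)) stop(name, " is not symmetric positive definite")
  invisible(S)
}

.assertSameDim <- function(S1, S2) {
  if (!all(dim(S1) == dim(S2))) stop("dimension mismatch between SPD matrices")
  invisible(NULL)
}

#' Spatial covariance descriptor of an EEG segment
#'
#' Computes `X %*% t(X) / (T - 1)` for a channels x samples segment, the SPD
#' descriptor on which the whole pipeline operates. An optional shrinkage
#' toward the scaled identity (`(1 - s) C + s * mean(diag(C)) * I`) guarantees
#' strict positive definiteness for rank-deficient segments.
#'
#' @param X numeric matrix, channels x samples (samples >= 2, all finite)
#' @param shrinkage shrinkage weight in `[0, 1)` toward the scaled identity
#' @return an SPD matrix (channels x channels)
#' @examples
#' X <- matrix(rnorm(8 * 200), 8)
#' C <- covDescriptor(X)
#' isSPD(C)
#' @export
covDescriptor <- function(X, shrinkage = 0) {
  if (!is.matrix(X) || ncol(X) < 2) stop("X must be a matrix with >= 2 samples")
  if (!all(is.finite(X))) stop("non-finite values in segment")
  if (shrinkage < 0 || shrinkage >= 1) stop("shrinkage must lie in [0, 1)")
  C <- tcrossprod(X) / (ncol(X) - 1)
  if (shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * mean(diag(C)) * diag(nrow(C))
  }
  C <- .symmetrize(C)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("degenerate segment: covariance not positive definite ",
         "(rank-deficient input with shrinkage 0?)")
  }
  C
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `sqrt(sum(log(lambda_i)^2))` over the generalized eigenvalues lambda_i of
#' the pencil (S2, S1). Invariant to congruence by any invertible matrix and
#' to joint inversion.
#'
#' @param S1,S2 SPD matrices of equal dimension
#' @return non-negative scalar distance
#' @examples
#' riemannDistance(diag(2), diag(c(exp(2), 1)))  # = 2
#' @export
riemannDistance <- function(S1, S2) {
  .assertSPD(S1); .assertSPD(S2); .assertSameDim(S1, S2)
  ih <- .matPow(S1, -0.5, warn = FALSE)
  M <- .symmetrize(ih %*% S2 %*% ih)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, 1e-300))^2))
}

#' Logarithmic map to the tangent space at a reference point
#'
#' Returns the tangent vector `log(C^{-1/2} S C^{-1/2})` of `S` at the
#' reference `C`, as a [TangentVector-class]. [expMap()] inverts it.
#'
#' @param S SPD matrix to map
#' @param C SPD reference point
#' @return a [TangentVector-class]
#' @export
logMap <- function(S, C) {
  .assertSPD(S); .assertSPD(C); .assertSameDim(S, C)
  new("TangentVector", mat = .logMapMat(S, C), ref = C)
}

# matrix-form log map, no S4 overhead (hot path)
.logMapMat <- function(S, C) {
  ih <- .matPow(C, -0.5, warn = FALSE)
  .matLog(.symmetrize(ih %*% S %*% ih), warn = FALSE)
}

# matrix-form exp map
.expMapMat <- function(Tm, C) {
  h <- .matPow(C, 0.5, warn = FALSE)
  .symmetrize(h %*% .matExp(Tm) %*% h)
}

#' Exponential map from the tangent space back to the manifold
#'
#' Returns `C^{1/2} exp(T) C^{1/2}`, always SPD. `T` may be a
#' [TangentVector-class] (its stored reference must match `C` when `C` is
#' given) or a plain symmetric matrix.
#'
#' @param T a [TangentVector-class] or symmetric matrix
#' @param C SPD reference point; defaults to the tangent vector's own
#'   reference
#' @return an SPD matrix
#' @export
expMap <- function(T, C = NULL) {
  if (is(T, "TangentVector")) {
    if (is.null(C)) C <- T@ref
    else if (max(abs(C - T@ref)) > 1e-8 * (1 + max(abs(C))))
      stop("reference of the tangent vector differs from C")
    Tm <- T@mat
  } else {
    if (is.null(C)) stop("a reference point C is required for a raw matrix")
    Tm <- .symmetrize(T)
  }
  .assertSPD(C)
  .assertSameDim(Tm, C)
  .expMapMat(Tm, C)
}

#' Isometric half-vectorization of a tangent vector
#'
#' Stacks the diagonal (unit weight) and the upper off-diagonal entries
#' (weight sqrt(2)) so that the Euclidean norm of the feature vector equals
#' the Frobenius norm of the symmetric matrix it encodes. This is the feature
#' vector fed to the RVM; length n(n+1)/2.
#'
#' @param T a [TangentVector-class] or symmetric matrix
#' @param offDiagWeight weight applied to off-diagonal entries; the default
#'   sqrt(2) makes the map an isometry (tangent Euclidean distance equals the
#'   Frobenius distance of the encoded matrices)
#' @return numeric vector of length n(n+1)/2
#' @export
tangentVectorize <- function(T, offDiagWeight = sqrt(2)) {
  Tm <- if (is(T, "TangentVector")) T@mat else .symmetrize(T)
  n <- nrow(Tm)
  up <- upper.tri(Tm)
  c(diag(Tm), offDiagWeight * Tm[up])
}

#' Tangent-space approximation of the Riemannian distance
#'
#' Euclidean distance between the vectorized tangent vectors of `S1` and `S2`
#' taken at the common reference `C`. Equals the affine-invariant distance
#' exactly when `S1`, `S2`, `C` commute, and approximates it locally
#' otherwise.
#'
#' @param S1,S2 SPD matrices
#' @param C SPD reference point
#' @return non-negative scalar
#' @export
tangentDistance <- function(S1, S2, C) {
  .assertSPD(C)
  t1 <- tangentVectorize(.logMapMat(S1, C))
  t2 <- tangentVectorize(.logMapMat(S2, C))
  sqrt(sum((t1 - t2)^2))
}

#' Karcher (Riemannian geometric) mean of SPD matrices
#'
#' Iterative tangent-space averaging: initialize at the arithmetic mean, map
#' all matrices to the tangent space at the current estimate, take the
#' Euclidean mean of the tangent vectors, map it back with the exponential
#' map, and stop once the mean tangent vector's Frobenius norm falls below
#' `tol` (at that point the estimate is the Fréchet mean: the mean tangent
#' vector vanishes).
#'
#' @param covs list of SPD matrices of common dimension
#' @param tol convergence tolerance on the mean tangent norm
#' @param maxIter maximum number of iterations
#' @return SPD matrix, the Karcher mean
#' @examples
#' karcherMean(list(diag(c(1, 4)), diag(c(4, 1))))  # diag(2, 2)
#' @export
karcherMean <- function(covs, tol = 1e-6, maxIter = 50L) {
  if (!length(covs)) stop("empty set of covariances")
  if (tol <= 0) stop("tol must be positive")
  n <- length(covs)
  d <- nrow(covs[[1]])
  for (C in covs) {
    if (!all(dim(C) == c(d, d))) stop("dimension mismatch in covariance set")
  }
  if (n == 1L) return(.symmetrize(covs[[1]]))
  M <- .symmetrize(Reduce(`+`, covs) / n)
  for (it in seq_len(maxIter)) {
    ih <- .matPow(M, -0.5, warn = FALSE)
    h <- .matPow(M, 0.5, warn = FALSE)
    Tbar <- matrix(0, d, d)
    for (C in covs) {
      Tbar <- Tbar + .matLog(.symmetrize(ih %*% C %*% ih), warn = FALSE)
    }
    Tbar <- Tbar / n
    resid <- sqrt(sum(Tbar^2))
    if (resid < tol) return(M)
    M <- .symmetrize(h %*% .matExp(Tbar) %*% h)
  }
  stop(sprintf(
    "Karcher mean did not converge in %d iterations (last residual %.3g)",
    maxIter, resid))
}

#' Tangent-space feature matrix of a set of covariances
#'
#' Maps each covariance to the tangent space at `ref` (the set's Karcher mean
#' by default) and stacks the isometric vectorizations row-wise; the feature
#' matrix consumed by the RVM.
#'
#' @param covs list of SPD matrices
#' @param ref SPD reference point; defaults to `karcherMean(covs)`
#' @return list with `features` (n x d(d+1)/2 matrix) and `ref` (the
#'   reference used)
#' @export
tangentFeatures <- function(covs, ref = NULL) {
  if (is.null(ref)) ref <- karcherMean(covs)
  ih <- .matPow(ref, -0.5, warn = FALSE)
  feats <- t(vapply(covs, function(C) {
    tangentVectorize(.matLog(.symmetrize(ih %*% C %*% ih), warn = FALSE))
  }, numeric(nrow(ref) * (nrow(ref) + 1) / 2)))
  list(features = feats, ref = ref)
}
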