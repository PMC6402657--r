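# Multi-class common spatial patterns: whitening, approximate joint
# diagonalization of the class-mean covariances (Jacobi angles), and
# mutual-information ranking of the components.

# Approximate joint diagonalization of a list of symmetric matrices by
# Givens rotations (Jacobi-angle scheme). Returns the orthogonal matrix V
# such that t(V) %*% A %*% V is approximately diagonal for every A.
.jointDiagonalize <- function(mats, tol = 1e-10, maxSweeps = 100L) {
  d <- nrow(mats[[1]])
  V <- diag(d)
  A <- lapply(mats, function(m) (m + t(m)) / 2)
  for (sweep in seq_len(maxSweeps)) {
    maxRot <- 0
    for (p in 1:(d - 1)) {
      for (q in (p + 1):d) {
        g1 <- vapply(A, function(m) m[p, p] - m[q, q], numeric(1))
        g2 <- vapply(A, function(m) m[p, q] + m[q, p], numeric(1))
        ton <- sum(g1 * g1 - g2 * g2)
        toff <- sum(g1 * g2)
        theta <- 0.5 * atan2(2 * toff, ton + sqrt(ton * ton + 4 * toff * toff))
        cth <- cos(theta); sth <- sin(theta)
        if (abs(sth) > tol) {
          maxRot <- max(maxRot, abs(sth))
          G <- diag(d)
          G[p, p] <- cth; G[q, q] <- cth
          G[p, q] <- -sth; G[q, p] <- sth
          A <- lapply(A, function(m) crossprod(G, m) %*% G)
          V <- V %*% G
        }
      }
    }
    if (maxRot < tol) break
  }
  V
}

# Gaussian-approximation mutual information (bits) between a scalar feature
# and the class label: MI = H(marginal) - sum_c pi_c H(f | c), both entropies
# under a Gaussian fit. Stable at a few hundred samples per class.
.gaussMI <- function(f, labels) {
  classes <- sort(unique(labels))
  vTot <- stats::var(f)
  if (vTot <= 0) return(0)
  hCond <- 0
  for (c in classes) {
    fc <- f[labels == c]
    vc <- stats::var(fc)
    if (vc <= 0) vc <- 1e-12
    hCond <- hCond + length(fc) / length(f) * 0.5 * log2(vc)
  }
  max(0, 0.5 * log2(vTot) - hCond)
}

#' Fit a multi-class common spatial pattern filter
#'
#' (1) whitens with the pooled (balanced class-mean) covariance, (2)
#' approximately jointly diagonalizes the whitened class-mean covariances by
#' a Jacobi-angle scheme, (3) scores each resulting component by the
#' Gaussian-approximation mutual information between its per-segment
#' log-variance and the class label, (4) keeps the `d` top-scoring
#' components, columns ordered by score (ties broken by lower component
#' index).
#'
#' @param covs list of full-channel SPD covariance matrices, one per segment
#' @param labels integer class label per segment (>= 2 classes present)
#' @param d number of components to retain (<= channel count)
#' @param sourceRun run index recorded in the filter
#' @return a [SpatialFilter-class]
#' @export
fitSpatialFilter <- function(covs, labels, d = 12L, sourceRun = -1L) {
  D <- nrow(covs[[1]])
  d <- as.integer(d)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (d > D) stop("cannot retain more components than channels")
  if (length(covs) < d) stop("need at least d segments")
  classMeans <- lapply(classes, function(c) {
    idx <- which(labels == c)
    if (!length(idx)) stop("class ", c, " has no segments")
    Reduce(`+`, covs[idx]) / length(idx)
  })
  pooled <- Reduce(`+`, classMeans) / length(classMeans)
  ev <- eigen(.symmetrize(pooled), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) {
    stop("singular pooled covariance; apply covariance shrinkage upstream")
  }
  Pw <- .matPow(pooled, -0.5, warn = FALSE)
  white <- lapply(classMeans, function(m) .symmetrize(Pw %*% m %*% Pw))
  V <- .jointDiagonalize(white)
  Wfull <- Pw %*% V
  # per-component log-variance over segments, scored by MI with the label
  logVar <- vapply(seq_len(D), function(j) {
    w <- Wfull[, j]
    log(vapply(covs, function(C) max(drop(crossprod(w, C %*% w)), 1e-300),
               numeric(1)))
  }, numeric(length(covs)))
  scores <- vapply(seq_len(D), function(j) .gaussMI(logVar[, j], labels),
                   numeric(1))
  ord <- order(-scores, seq_len(D))[seq_len(d)]
  new("SpatialFilter", W = Wfull[, ord, drop = FALSE], scores = scores[ord],
      sourceRun = as.integer(sourceRun))
}

#' Apply a spatial filter to a segment
#'
#' `Z = t(W) %*% X`; the covariance of the filtered data equals
#' `t(W) %*% C %*% W`.
#'
#' @param filter a [SpatialFilter-class]
#' @param x channels x samples matrix
#' @return d x samples matrix
#' @export
applySpatialFilter <- function(filter, x) {
  if (nrow(x) != nrow(filter@W)) stop("channel count mismatch")
  crossprod(filter@W, x)
}

#' Project a full-channel covariance through a spatial filter
#'
#' @param filter a [SpatialFilter-class] (or a plain D x d matrix)
#' @param C full-channel SPD covariance
#' @return d x d SPD covariance `t(W) %*% C %*% W`
#' @export
projectCovariance <- function(filter, C) {
  W <- if (is(filter, "SpatialFilter")) filter@W else filter
  if (nrow(C) != nrow(W)) stop("channel count mismatch")
  .symmetrize(crossprod(W, C %*% W))
}
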