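# Evaluation suite: confusion-matrix quality, pairwise class separability,
# instability via tangent-space PCA, exact left-tail Wilcoxon signed-rank
# tests, and per-subject regression of quality over runs.

#' Row-normalized confusion matrix
#'
#' Rows are true classes, entries the fraction of that class's segments
#' predicted as each class (class-wise recall). Classes with no true samples
#' get an all-zero row.
#'
#' @param truth integer vector of true labels in 1..nClasses
#' @param predicted integer vector of predicted labels
#' @param nClasses number of classes (default 4)
#' @param counts if TRUE return raw counts instead of row-normalized fractions
#' @return nClasses x nClasses matrix
#' @export
confusionMatrix <- function(truth, predicted, nClasses = 4L, counts = FALSE) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  Q <- matrix(0, nClasses, nClasses)
  for (i in seq_along(truth)) {
    Q[truth[i], predicted[i]] <- Q[truth[i], predicted[i]] + 1
  }
  if (counts) return(Q)
  rs <- rowSums(Q)
  Q[rs > 0, ] <- Q[rs > 0, , drop = FALSE] / rs[rs > 0]
  Q
}

#' Quality of a confusion matrix
#'
#' `min(diag(Q)) / mean(diag(Q))` for a row-normalized confusion matrix:
#' 1 when all class-wise accuracies are equal, 0 when at least one class is
#' never recognized. Unlike the average accuracy, it penalizes classifiers
#' whose performance is biased toward a few classes (a constant predictor
#' scores 25% accuracy on four balanced classes but quality 0).
#'
#' @param Q row-normalized confusion matrix (or an object coercible to one)
#' @return scalar in `[0, 1]`
#' @examples
#' confusionQuality(diag(4) * 0.5 + 0.125)  # balanced -> 1
#' @export
confusionQuality <- function(Q) {
  q <- diag(as.matrix(Q))
  if (all(q == 0)) return(0)
  min(q) / mean(q)
}

#' Riemannian separability between two classes of covariances
#'
#' `d(mu_A, mu_B) / (sigma_A * sigma_B)` where mu are the per-class Karcher
#' means, d the affine-invariant Riemannian distance, and sigma the standard
#' deviation of each class's member-to-own-mean distances. Larger values mean
#' more discriminable classes.
#'
#' @param covsA,covsB lists of SPD matrices (>= 2 per class)
#' @return non-negative scalar
#' @export
classSeparability <- function(covsA, covsB) {
  if (length(covsA) < 2 || length(covsB) < 2)
    stop("each class needs at least 2 covariance samples")
  muA <- karcherMean(covsA)
  muB <- karcherMean(covsB)
  dA <- vapply(covsA, riemannDistance, numeric(1), S2 = muA)
  dB <- vapply(covsB, riemannDistance, numeric(1), S2 = muB)
  sA <- stats::sd(dA)
  sB <- stats::sd(dB)
  if (sA == 0 || sB == 0)
    stop("degenerate class: zero spread of distances to the class mean")
  riemannDistance(muA, muB) / (sA * sB)
}

#' Instability of a class of covariances
#'
#' Number of principal components needed to represent 95% of the class's
#' tangent-space variance: all covariances are mapped to the tangent space at
#' the class Karcher mean, PCA is run on the vectorized tangent vectors, and
#' the smallest component count whose cumulative explained variance reaches
#' the threshold (inclusive) is returned. High values indicate scattered,
#' exploratory data; a class of identical covariances has zero variance and
#' instability 0.
#'
#' @param covs list of SPD matrices (>= 2)
#' @param threshold cumulative explained-variance threshold (default 0.95)
#' @return non-negative integer
#' @export
classInstability <- function(covs, threshold = 0.95) {
  if (length(covs) < 2) stop("need at least 2 covariance samples")
  tf <- tangentFeatures(covs)
  X <- tf$features
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = 0, nv = 0)$d
  var <- sv^2
  tot <- sum(var)
  if (tot <= 1e-24) return(0L)
  as.integer(which(cumsum(var) / tot >= threshold)[1])
}

#' Exact left-tail Wilcoxon signed-rank test
#'
#' Tests H1: `before < after` on paired values by exact enumeration of the
#' signed-rank null. Differences `before - after` equal to zero are dropped;
#' tied absolute differences receive mid-ranks; the p-value is the exact
#' probability, over all 2^n sign assignments, that the positive-rank sum is
#' at most the observed one. Computed by dynamic programming over the
#' (half-integer) rank lattice, which is identical to full enumeration.
#'
#' @param before,after paired numeric vectors
#' @return exact p-value in (0, 1]
#' @examples
#' wilcoxonLeftExact(1:8, 2:9)  # all improved: 1/256
#' @export
wilcoxonLeftExact <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors differ in length")
  d <- before - after
  if (!all(is.finite(d))) stop("non-finite differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))           # mid-ranks on ties
  w <- sum(r[d > 0])          # positive-rank sum of before - after
  # exact null distribution over all sign assignments; double ranks so the
  # lattice is integer even with mid-ranks
  r2 <- as.integer(round(2 * r))
  maxS <- sum(r2)
  counts <- numeric(maxS + 1)
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(maxS + 1 - ri)])
    counts <- counts + shifted
  }
  w2 <- round(2 * w)
  sum(counts[seq_len(w2 + 1)]) / 2^n
}

#' Full-enumeration signed-rank oracle (reference implementation)
#'
#' Brute-force version of [wilcoxonLeftExact()] that enumerates all 2^n sign
#' assignments explicitly; usable for n <= 20. Kept as an independent check
#' of the dynamic-programming tail computation.
#'
#' @inheritParams wilcoxonLeftExact
#' @return exact p-value
#' @export
wilcoxonLeftEnum <- function(before, after) {
  d <- before - after
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n > 20) stop("enumeration oracle limited to n <= 20")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0
    if (sum(r[signs]) <= w + 1e-9) total <- total + 1L
  }
  total / 2^n
}

#' Linear regression of a quality score over run index
#'
#' Ordinary least squares of `y = a * r + b` with the run index
#' (1, 2, ..., length(y)) as regressor; used to summarize each subject's
#' improvement over the
#' constrained-feedback runs.
#'
#' @param y numeric vector of per-run scores
#' @param runs run indices (default `1:length(y)`)
#' @return named numeric vector `c(a = slope, b = intercept)`
#' @export
regressOverRuns <- function(y, runs = seq_along(y)) {
  if (length(y) < 2) stop("need at least 2 points")
  fit <- stats::lm(y ~ runs)
  c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
}

#' Round the way the evaluation tables print
#'
#' p-values print with 3 decimals when below 0.01 and 2 otherwise;
#' quality/accuracy scores with 1 decimal.
#'
#' @param x numeric vector
#' @param what `"p"` or `"score"`
#' @return rounded numeric vector
#' @export
tableRound <- function(x, what = c("p", "score")) {
  what <- match.arg(what)
  if (what == "score") return(round(x, 1))
  ifelse(x < 0.01, round(x, 3), round(x, 2))
}

#' Accuracy equivalent of a Cohen's kappa level
#'
#' For balanced chance level `1/nClasses`, `kappa = (acc - chance) /
#' (1 - chance)`; inverting gives the accuracy a given kappa corresponds to
#' (kappa 0.4 on four classes corresponds to 55% accuracy).
#'
#' @param kappa Cohen's kappa
#' @param nClasses number of balanced classes
#' @return accuracy as a fraction
#' @export
kappaToAccuracy <- function(kappa, nClasses = 4L) {
  chance <- 1 / nClasses
  chance + kappa * (1 - chance)
}
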