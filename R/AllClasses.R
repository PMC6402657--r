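#' @import methods
NULL

#' Tangent vector at a reference point on the SPD manifold
#'
#' Encodes `log(C^{-1/2} S C^{-1/2})` for an SPD matrix `S` taken at the
#' reference point `C`. The symmetric matrix form is kept in `mat`; the
#' isometric half-vectorization (off-diagonals weighted by sqrt(2)) is
#' obtained with [tangentVectorize()].
#'
#' @slot mat symmetric matrix, the tangent vector in matrix form
#' @slot ref SPD matrix, the reference point at which the log map was taken
#' @exportClass TangentVector
setClass("TangentVector",
  representation(mat = "matrix", ref = "matrix"),
  validity = function(object) {
    if (!all(dim(object@mat) == dim(object@ref)))
      return("tangent matrix and reference must have the same dimension")
    if (max(abs(object@mat - t(object@mat))) > 1e-8 * (1 + max(abs(object@mat))))
      return("tangent matrix must be symmetric")
    TRUE
  }
)

#' Multi-class common spatial pattern filter
#'
#' A D x d spatial filter learned by whitening, approximate joint
#' diagonalization of the class-mean covariances, and mutual-information
#' ranking of the resulting components.
#'
#' @slot W D x d filter matrix; column i extracts component i as `W[, i] %*% X`
#' @slot scores mutual-information score (bits) of each retained component,
#'   non-increasing down the columns
#' @slot sourceRun index of the run the filter was fitted on (-1 if unknown)
#' @exportClass SpatialFilter
setClass("SpatialFilter",
  representation(W = "matrix", scores = "numeric", sourceRun = "integer"),
  validity = function(object) {
    if (ncol(object@W) != length(object@scores))
      return("one score per retained component required")
    if (ncol(object@W) > nrow(object@W))
      return("cannot retain more components than channels")
    if (length(object@scores) > 1 && any(diff(object@scores) > 1e-8))
      return("component scores must be non-increasing")
    TRUE
  }
)

#' Sparse multinomial-probit relevance vector machine
#'
#' Multi-class RVM trained on tangent-space features with a Gaussian kernel.
#' Only the retained relevance vectors and their class weights are stored.
#'
#' @slot relVectors matrix of retained training features (rows = relevance
#'   vectors)
#' @slot weights relevance-vector x class weight matrix
#' @slot sigma Gaussian kernel bandwidth (same units as the feature space)
#' @slot nClasses number of classes
#' @slot relIndex indices of the relevance vectors in the original training set
#' @exportClass RVMModel
setClass("RVMModel",
  representation(relVectors = "matrix", weights = "matrix", sigma = "numeric",
                 nClasses = "integer", relIndex = "integer"),
  validity = function(object) {
    if (nrow(object@relVectors) != nrow(object@weights))
      return("one weight row per relevance vector required")
    if (ncol(object@weights) != object@nClasses)
      return("one weight column per class required")
    if (object@sigma <= 0) return("kernel bandwidth must be positive")
    TRUE
  }
)

#' One sub-model of the adaptive mixture
#'
#' Bundles a trained RVM with the spatial filter and reference Karcher mean it
#' was trained under, the representative-sample count k, its prior weight and
#' its cross-validated confusion-matrix quality.
#'
#' @slot rvm the trained [RVMModel-class]
#' @slot filter the [SpatialFilter-class] applied before covariance extraction
#' @slot mu reference Karcher mean (d x d SPD matrix) of the training
#'   covariances; tangent features are taken at this point
#' @slot prior prior weight a >= 0 (confusion-matrix quality on the most
#'   recent run; 0 when suppressed)
#' @slot qcm confusion-matrix quality score in `[0, 1]` (NA before the first
#'   cross-validation)
#' @slot k representative segments kept per trial when the model was trained
#' @slot run index of the source run
#' @exportClass SubModel
setClass("SubModel",
  representation(rvm = "RVMModel", filter = "SpatialFilter", mu = "matrix",
                 prior = "numeric", qcm = "numeric", k = "integer",
                 run = "integer"),
  validity = function(object) {
    if (nrow(object@mu) != ncol(object@filter@W))
      return("reference mean dimension must equal the filter's component count")
    if (object@prior < 0) return("prior weight must be non-negative")
    TRUE
  }
)

#' Adaptively weighted mixture of RVM sub-models
#'
#' Ordered set of [SubModel-class]s with the suppression threshold epsilon.
#' Time-varying weights are computed during prediction from the priors and the
#' running mean Riemannian distance of incoming covariances to each sub-model's
#' reference mean (see [mixturePredict()]).
#'
#' @slot submodels list of [SubModel-class]
#' @slot epsilon suppression threshold: sub-models whose confusion-matrix
#'   quality on the latest run falls below epsilon get prior 0
#' @exportClass RVMMixture
setClass("RVMMixture",
  representation(submodels = "list", epsilon = "numeric"),
  validity = function(object) {
    if (!all(vapply(object@submodels, is, logical(1), class2 = "SubModel")))
      return("submodels must all be SubModel objects")
    if (object@epsilon < 0 || object@epsilon >= 1)
      return("epsilon must lie in [0, 1)")
    TRUE
  }
)

#' A recorded (or generated) multi-run EEG session
#'
#' Trials are stored as channel x sample matrices with per-trial label, trial
#' and run bookkeeping. Generated sessions additionally carry the generator's
#' ground truth (class prototypes per run, per-trial means, outlier flags).
#'
#' @slot trials list of channel x sample numeric matrices (microvolts)
#' @slot info data.frame with one row per trial: `label` (1..4), `trial`
#'   (index within run), `run` (0-based run index)
#' @slot rate sampling rate in Hz
#' @slot groundTruth list of generator ground truth, or empty list for
#'   recorded data
#' @slot provenance character log of preprocessing steps applied
#' @exportClass EEGSession
setClass("EEGSession",
  representation(trials = "list", info = "data.frame", rate = "numeric",
                 groundTruth = "list", provenance = "character"),
  validity = function(object) {
    if (length(object@trials) != nrow(object@info))
      return("one info row per trial required")
    if (!all(c("label", "trial", "run") %in% names(object@info)))
      return("info must have columns label, trial, run")
    if (nrow(object@info) && !all(object@info$label %in% 1:4))
      return("labels must be in 1..4")
    if (object@rate <= 0) return("sampling rate must be positive")
    TRUE
  }
)

#' Configuration of the synthetic session generator
#'
#' Defaults emulate the acquisition protocol the pipeline was designed for:
#' 60 analysis channels at 256 Hz, 7 runs of 40 ten-second trials (10 per
#' class), predictions every 0.25 s on 2 s windows. The discriminative signal
#' lives entirely in the spatial covariance: class prototypes are placed on
#' the SPD manifold at geodesic magnitude `separation` from a common AR(1)
#' base covariance, trials scatter around their class prototype with tangent
#' dispersion `tau`, prototypes drift between runs by `drift`, and the
#' dispersion contracts run-to-run by the exploitation factor `gamma`.
#'
#' @slot nChannels number of channels
#' @slot rate sampling rate (Hz)
#' @slot nRuns number of runs in the session
#' @slot trialsPerClass trials per class per run
#' @slot trialSec trial duration (s)
#' @slot windowSec segment window length (s)
#' @slot stepSec segment step (s)
#' @slot separation geodesic magnitude of class prototypes from the base
#'   covariance (unitless, tangent-space norm)
#' @slot tau initial trial-level tangent dispersion
#' @slot drift run-to-run prototype drift magnitude
#' @slot gamma exploitation factor in (0, 1]: tau is multiplied by gamma after
#'   each run
#' @slot pOut probability that a trial receives an implanted outlier span
#' @slot seed integer seed fixing the whole session
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(nChannels = "integer", rate = "numeric", nRuns = "integer",
                 trialsPerClass = "integer", trialSec = "numeric",
                 windowSec = "numeric", stepSec = "numeric",
                 separation = "numeric", tau = "numeric", drift = "numeric",
                 gamma = "numeric", pOut = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nChannels < 2) return("need at least 2 channels")
    if (object@gamma <= 0 || object@gamma > 1)
      return("gamma must lie in (0, 1]")
    if (object@pOut < 0 || object@pOut > 1)
      return("pOut must be a probability")
    if (any(c(object@separation, object@tau, object@drift) < 0))
      return("magnitudes must be non-negative")
    TRUE
  }
)

setMethod("show", "TangentVector", function(object) {
  cat(sprintf("TangentVector: %d x %d symmetric, |T|_F = %.4g\n",
              nrow(object@mat), ncol(object@mat),
              sqrt(sum(object@mat^2))))
})

setMethod("show", "SpatialFilter", function(object) {
  cat(sprintf("SpatialFilter: %d channels -> %d components (run %d)\n",
              nrow(object@W), ncol(object@W), object@sourceRun))
  cat("  MI scores (bits):", paste(sprintf("%.3f", object@scores),
                                   collapse = " "), "\n")
})

setMethod("show", "RVMModel", function(object) {
  cat(sprintf("RVMModel: %d relevance vectors, %d classes, sigma = %.4g\n",
              nrow(object@relVectors), object@nClasses, object@sigma))
})

setMethod("show", "SubModel", function(object) {
  cat(sprintf(
    "SubModel (run %d, k = %d): prior = %.3f, qcm = %s, %d relevance vectors\n",
    object@run, object@k, object@prior,
    ifelse(is.na(object@qcm), "NA", sprintf("%.3f", object@qcm)),
    nrow(object@rvm@relVectors)))
})

setMethod("show", "RVMMixture", function(object) {
  cat(sprintf("RVMMixture of %d sub-models (epsilon = %.2f)\n",
              length(object@submodels), object@epsilon))
  for (sm in object@submodels) show(sm)
})

setMethod("show", "EEGSession", function(object) {
  cat(sprintf("EEGSession: %d trials, %d runs, %d channels @ %g Hz\n",
              length(object@trials), length(unique(object@info$run)),
              if (length(object@trials)) nrow(object@trials[[1]]) else 0,
              object@rate))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d ch @ %g Hz, %d runs x %d trials/class, sep %.2f, tau %.2f, drift %.2f, gamma %.2f, pOut %.2f, seed %d\n",
    object@nChannels, object@rate, object@nRuns, object@trialsPerClass,
    object@separation, object@tau, object@drift, object@gamma, object@pOut,
    object@seed))
})

# ---- accessors ----

#' Accessors for pipeline objects
#'
#' Small read-only accessors for the S4 containers: the filter matrix, MI
#' scores, sub-model list, priors and trial metadata.
#'
#' @param object an S4 object of this package
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
filterMatrix <- function(object) {
  stopifnot(is(object, "SpatialFilter"))
  object@W
}

#' @rdname accessors
#' @export
miScores <- function(object) {
  stopifnot(is(object, "SpatialFilter"))
  object@scores
}

#' @rdname accessors
#' @export
subModels <- function(object) {
  stopifnot(is(object, "RVMMixture"))
  object@submodels
}

#' @rdname accessors
#' @export
priors <- function(object) {
  stopifnot(is(object, "RVMMixture"))
  vapply(object@submodels, function(s) s@prior, numeric(1))
}

#' @rdname accessors
#' @export
trialInfo <- function(object) {
  stopifnot(is(object, "EEGSession"))
  object@info
}

#' @rdname accessors
#' @export
trialData <- function(object) {
  stopifnot(is(object, "EEGSession"))
  object@trials
}

#' @rdname accessors
#' @export
samplingRate <- function(object) {
  stopifnot(is(object, "EEGSession"))
  object@rate
}

#' @rdname accessors
#' @export
groundTruth <- function(object) {
  stopifnot(is(object, "EEGSession"))
  object@groundTruth
}
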