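# The adaptive core: representative-sample selection around per-trial
# Karcher means, sub-model training, cross-validated choice of k, mixture
# maintenance with confusion-quality priors and distance-driven online
# weights, and the run/trial feedback replay.

#' Construct a sub-model
#'
#' @param rvm an [RVMModel-class]
#' @param filter a [SpatialFilter-class]
#' @param mu reference Karcher mean of the training covariances (after
#'   filtering)
#' @param k representative segments per trial used in training
#' @param run source-run index
#' @param prior prior weight (default 1)
#' @param qcm cross-validated confusion quality (NA until evaluated)
#' @return a [SubModel-class]
#' @export
SubModel <- function(rvm, filter, mu, k, run, prior = 1, qcm = NA_real_) {
  new("SubModel", rvm = rvm, filter = filter, mu = mu,
      prior = as.numeric(prior), qcm = as.numeric(qcm), k = as.integer(k),
      run = as.integer(run))
}

#' Construct a mixture of sub-models
#'
#' @param submodels list of [SubModel-class]
#' @param epsilon suppression threshold on confusion quality (default 0.25)
#' @return an [RVMMixture-class]
#' @export
RVMMixture <- function(submodels, epsilon = 0.25) {
  new("RVMMixture", submodels = submodels, epsilon = as.numeric(epsilon))
}

#' Select representative segments of a trial
#'
#' Computes the Karcher mean of the trial's segment covariances and returns
#' the indices of the `k` covariances nearest to it under the Riemannian
#' distance (ties broken by lower segment index). Because a user repeats the
#' same mental pattern within a trial, segments far from the trial mean are
#' distraction/noise and are left out.
#'
#' @param covs list of SPD covariances of one trial's segments (after
#'   spatial filtering)
#' @param k number of representatives, `1 <= k <= length(covs)`
#' @param mu optional precomputed trial Karcher mean
#' @return integer indices of the selected segments, in ascending order
#' @export
selectRepresentatives <- function(covs, k, mu = NULL) {
  n <- length(covs)
  if (k < 1 || k > n) stop("k out of range 1..", n)
  if (is.null(mu)) mu <- karcherMean(covs)
  d <- vapply(covs, riemannDistance, numeric(1), S2 = mu)
  sort(order(d, seq_len(n))[seq_len(k)])
}

#' Pre-filter segments by previous-model confidence
#'
#' Keeps segments whose true-class probability under the previous mixture
#' exceeds `epsF`. Choosing `epsF` below chance (default 0.1 < 0.25) rejects
#' only certainly-noisy samples while leaving the new run's data selection
#' as independent of earlier models as possible. With no previous model
#' (`probTrue = NULL`) everything is kept.
#'
#' @param probTrue per-segment probability of the true class under the
#'   previous mixture (e.g. from [mixtureReplay()]), or NULL
#' @param epsF rejection threshold in `[0, 1)`
#' @param n number of segments (used when `probTrue` is NULL)
#' @return logical keep vector
#' @export
prefilterSegments <- function(probTrue = NULL, epsF = 0.1, n = NULL) {
  if (epsF < 0 || epsF >= 1) stop("epsF must lie in [0, 1)")
  if (is.null(probTrue)) {
    if (is.null(n)) stop("n required when probTrue is NULL")
    return(rep(TRUE, n))
  }
  probTrue > epsF
}

# Shared per-trial machinery for one run: prefilter, project through the
# initial filter, per-trial Karcher means. Returns everything the per-k
# selection needs.
.runSelectionState <- function(rc, filterInit, probTrue = NULL, epsF = 0.1,
                               kmTol = 1e-6, kmMaxIter = 50L) {
  keep <- prefilterSegments(probTrue, epsF, n = length(rc$covs))
  trials <- unique(rc$info$trial)
  for (tr in trials) {
    idx <- which(rc$info$trial == tr)
    if (!any(keep[idx])) {
      fallback <- if (is.null(probTrue)) idx[1] else idx[which.max(probTrue[idx])]
      keep[fallback] <- TRUE
      warning("trial ", tr, " lost all segments to the pre-filter; ",
              "keeping its highest-probability segment")
    }
  }
  proj <- lapply(rc$covs, projectCovariance, filter = filterInit)
  trialMeans <- lapply(trials, function(tr) {
    idx <- which(rc$info$trial == tr & keep)
    karcherMean(proj[idx], tol = kmTol, maxIter = kmMaxIter)
  })
  names(trialMeans) <- as.character(trials)
  list(keep = keep, proj = proj, trials = trials, trialMeans = trialMeans)
}

#' One pass of spatial-filter refinement and representative selection
#'
#' For one run of data: pre-filter by previous-model confidence, apply the
#' initial spatial filter, compute each trial's Karcher mean, keep the k
#' segments nearest the mean per trial, and refit the multi-class CSP on the
#' selected segments only. For run 0 the initial filter is fitted from all
#' segments of the run; for later runs it is the previous run's filter.
#'
#' @param rc run covariances as returned by [runCovariances()]
#' @param k representatives per trial
#' @param d CSP components to retain
#' @param filterInit initial [SpatialFilter-class]; NULL fits it from all
#'   segments of this run (run-0 initialization)
#' @param probTrue per-segment true-class probabilities from the previous
#'   mixture (NULL for run 0)
#' @param epsF pre-filter threshold
#' @param sourceRun run index stamped on the refitted filter
#' @return list with `filter` (refitted [SpatialFilter-class]), `selection`
#'   (per-trial list of selected within-run segment indices), `keep`
#'   (pre-filter mask)
#' @export
refineRunFilter <- function(rc, k, d = 12L, filterInit = NULL,
                            probTrue = NULL, epsF = 0.1, sourceRun = -1L) {
  if (is.null(filterInit)) {
    filterInit <- fitSpatialFilter(rc$covs, rc$info$label, d = d,
                                   sourceRun = sourceRun)
  }
  st <- .runSelectionState(rc, filterInit, probTrue, epsF)
  selection <- lapply(st$trials, function(tr) {
    idx <- which(rc$info$trial == tr & st$keep)
    kTr <- min(k, length(idx))
    pick <- selectRepresentatives(st$proj[idx], kTr,
                                  mu = st$trialMeans[[as.character(tr)]])
    idx[pick]
  })
  names(selection) <- as.character(st$trials)
  selIdx <- unlist(selection, use.names = FALSE)
  filter <- fitSpatialFilter(rc$covs[selIdx], rc$info$label[selIdx], d = d,
                             sourceRun = sourceRun)
  list(filter = filter, selection = selection, keep = st$keep)
}

.buildSubModel <- function(rc, selection, filter, k, run, ...) {
  selIdx <- unlist(selection, use.names = FALSE)
  covsSel <- lapply(rc$covs[selIdx], projectCovariance, filter = filter)
  mu <- karcherMean(covsSel)
  tf <- tangentFeatures(covsSel, ref = mu)
  rvm <- trainRVM(tf$features, rc$info$label[selIdx], ...)
  SubModel(rvm, filter, mu, k = k, run = run)
}

#' Train one sub-model on a run of data
#'
#' Full sub-model training: representative selection and filter refinement
#' ([refineRunFilter()]), covariance descriptors of the filtered selected
#' segments, Karcher reference mean, tangent-space features
#' (sqrt(2)-weighted vectorization) and a multinomial-probit RVM.
#'
#' @inheritParams refineRunFilter
#' @param run source-run index
#' @param ... further arguments to [trainRVM()]
#' @return a [SubModel-class]
#' @export
trainSubModel <- function(rc, k, d = 12L, filterInit = NULL, probTrue = NULL,
                          epsF = 0.1, run = -1L, ...) {
  ref <- refineRunFilter(rc, k, d, filterInit, probTrue, epsF,
                         sourceRun = run)
  .buildSubModel(rc, ref$selection, ref$filter, k = k, run = run, ...)
}

#' Train the candidate sub-models for a range of k
#'
#' Shares the pre-filter, initial projection and per-trial Karcher means
#' across candidates, then builds one sub-model per k.
#'
#' @inheritParams trainSubModel
#' @param kRange integer vector of candidate k values (default 8:12)
#' @return named list of [SubModel-class], names the k values
#' @export
trainCandidates <- function(rc, kRange = 8:12, d = 12L, filterInit = NULL,
                            probTrue = NULL, epsF = 0.1, run = -1L, ...) {
  if (is.null(filterInit)) {
    filterInit <- fitSpatialFilter(rc$covs, rc$info$label, d = d,
                                   sourceRun = run)
  }
  st <- .runSelectionState(rc, filterInit, probTrue, epsF)
  out <- list()
  for (k in kRange) {
    selection <- lapply(st$trials, function(tr) {
      idx <- which(rc$info$trial == tr & st$keep)
      kTr <- min(k, length(idx))
      pick <- selectRepresentatives(st$proj[idx], kTr,
                                    mu = st$trialMeans[[as.character(tr)]])
      idx[pick]
    })
    selIdx <- unlist(selection, use.names = FALSE)
    filter <- fitSpatialFilter(rc$covs[selIdx], rc$info$label[selIdx], d = d,
                               sourceRun = run)
    out[[as.character(k)]] <- .buildSubModel(rc, selection, filter, k = k,
                                             run = run, ...)
  }
  out
}

#' Per-segment class probabilities of one sub-model
#'
#' Projects each full-channel covariance through the sub-model's filter,
#' takes tangent features at its reference mean, and evaluates its RVM.
#'
#' @param sm a [SubModel-class]
#' @param covs list of full-channel SPD covariances
#' @return n x nClasses probability matrix
#' @export
subModelProbs <- function(sm, covs) {
  proj <- lapply(covs, projectCovariance, filter = sm@filter)
  tf <- tangentFeatures(proj, ref = sm@mu)
  predictProba(sm@rvm, tf$features)
}

#' Evaluate a sub-model on a run
#'
#' @param sm a [SubModel-class]
#' @param rc run covariances from [runCovariances()]
#' @return list with `accuracy`, `qcm`, `confusion` (row-normalized) and
#'   `pred`
#' @export
evaluateSubModel <- function(sm, rc) {
  P <- subModelProbs(sm, rc$covs)
  pred <- apply(P, 1, which.max)
  Q <- confusionMatrix(rc$info$label, pred, nClasses = sm@rvm@nClasses)
  list(accuracy = mean(pred == rc$info$label), qcm = confusionQuality(Q),
       confusion = Q, pred = pred)
}

#' Cross-validate the representative-sample count k
#'
#' Evaluates each candidate sub-model (trained on the previous run with a
#' different k) on all segments of the new run's data, ranks them by
#' confusion-matrix quality, and returns the best k (exact ties go to the
#' smaller k).
#'
#' @param candidates named list of [SubModel-class] (names/slots carry k)
#' @param rc the new run's covariances ([runCovariances()])
#' @return list with `k` (the argmax), `best` (its [SubModel-class]),
#'   `qcm` (named vector of candidate scores)
#' @export
crossValidateK <- function(candidates, rc) {
  if (!length(candidates)) stop("empty candidate set")
  ks <- vapply(candidates, function(s) s@k, integer(1))
  qcms <- vapply(candidates, function(s) evaluateSubModel(s, rc)$qcm,
                 numeric(1))
  ord <- order(-qcms, ks)
  best <- ord[1]
  list(k = unname(ks[best]), best = candidates[[best]],
       qcm = stats::setNames(unname(qcms), ks))
}

#' Update the mixture after a completed run
#'
#' Implements the between-run adaptation: (1) the run-(r-1) sub-model is
#' replaced by the candidate whose k cross-validates best on the new run's
#' data (skipped at the first update, where the calibration model keeps its
#' heuristic k = 9); (2) the run-r sub-model is appended, built with the
#' inferred k* (k* = 9 at the first update, otherwise the cross-validated
#' optimum, since the next run's data do not exist yet); (3) every older
#' sub-model's prior is set to its confusion quality p(Q) on the new run,
#' and the newest model's prior to the maximum of those; (4) priors below
#' the suppression threshold epsilon are zeroed (the newest model is never
#' suppressed).
#'
#' @param mixture the current [RVMMixture-class]
#' @param rc the completed run's covariances ([runCovariances()])
#' @param candidatesPrev candidate sub-models (varying k) trained on run
#'   r-1, or NULL at the first update
#' @param candidatesNew candidate sub-models trained on run r (the newest
#'   model is drawn from these at the inferred k*)
#' @param heuristicK k used when no previous cross-validation exists
#' @return list with `mixture` (updated [RVMMixture-class]), `kStar`,
#'   `cvQcm` (candidate scores, or NULL)
#' @export
updateMixture <- function(mixture, rc, candidatesPrev, candidatesNew,
                          heuristicK = 9L) {
  subs <- mixture@submodels
  cvQcm <- NULL
  if (is.null(candidatesPrev)) {
    kStar <- as.integer(heuristicK)
  } else {
    cv <- crossValidateK(candidatesPrev, rc)
    kStar <- cv$k
    cvQcm <- cv$qcm
    prevRun <- max(vapply(subs, function(s) s@run, integer(1)))
    which.prev <- which(vapply(subs, function(s) s@run, integer(1)) == prevRun)
    subs[[which.prev]] <- cv$best
  }
  ks <- vapply(candidatesNew, function(s) s@k, integer(1))
  if (!kStar %in% ks) stop("no candidate with k = ", kStar)
  newest <- candidatesNew[[which(ks == kStar)[1]]]
  # priors: p(Q_i) of every older model on this run's data
  pQ <- vapply(subs, function(s) evaluateSubModel(s, rc)$qcm, numeric(1))
  for (i in seq_along(subs)) {
    subs[[i]]@qcm <- pQ[i]
    subs[[i]]@prior <- if (pQ[i] < mixture@epsilon) 0 else pQ[i]
  }
  newest@prior <- if (length(pQ) && max(pQ) > 0) max(pQ) else 1
  newest@qcm <- NA_real_
  subs <- c(subs, list(newest))
  list(mixture = RVMMixture(subs, mixture@epsilon), kStar = kStar,
       cvQcm = cvQcm)
}

#' Fresh per-trial weight state of a mixture
#'
#' @param mixture an [RVMMixture-class]
#' @return list holding the running distance means (reset at trial onset)
#' @export
newTrialState <- function(mixture) {
  list(dbar = rep(NA_real_, length(mixture@submodels)), n = 0L)
}

# weights from priors and running mean distances over active sub-models
.mixtureWeights <- function(priorVec, dbar) {
  active <- priorVec > 0
  if (!any(active)) stop("all sub-model priors are zero")
  b <- numeric(length(priorVec))
  b[active] <- priorVec[active] / pmax(dbar[active], 1e-6)
  w <- b / sum(b)
  w
}

#' Online mixture prediction for one segment
#'
#' Maps the segment covariance through every sub-model's filter, updates the
#' within-trial running mean of Riemannian distances to each sub-model's
#' reference mean, forms weights `w_i = (a_i / dbar_i) / sum_j (a_j /
#' dbar_j)` over the active (non-suppressed) sub-models, and returns the
#' weighted class probabilities. The state is reset at each trial onset
#' ([newTrialState()]); the first segment's distance initializes the running
#' mean.
#'
#' @param mixture an [RVMMixture-class]
#' @param C full-channel SPD covariance of the segment
#' @param state per-trial state from [newTrialState()]
#' @return list with `probs` (length-nClasses), `pred`, `weights`, `state`
#' @export
mixturePredict <- function(mixture, C, state = NULL) {
  subs <- mixture@submodels
  if (is.null(state)) state <- newTrialState(mixture)
  m <- length(subs)
  dists <- numeric(m)
  P <- matrix(0, m, subs[[1]]@rvm@nClasses)
  for (i in seq_len(m)) {
    Ci <- projectCovariance(subs[[i]]@filter, C)
    dists[i] <- riemannDistance(Ci, subs[[i]]@mu)
    tf <- tangentVectorize(.logMapMat(Ci, subs[[i]]@mu))
    P[i, ] <- predictProba(subs[[i]]@rvm, tf)
  }
  n <- state$n + 1L
  dbar <- if (state$n == 0L) dists else (state$dbar * state$n + dists) / n
  w <- .mixtureWeights(vapply(subs, function(s) s@prior, numeric(1)), dbar)
  probs <- drop(crossprod(P, w))
  list(probs = probs, pred = which.max(probs), weights = w,
       state = list(dbar = dbar, n = n))
}

#' Replay a run through the mixture
#'
#' Batch equivalent of calling [mixturePredict()] segment-by-segment in
#' recording order with the weight state reset at every trial onset.
#' Per-sub-model probabilities and distances are computed in batch for
#' speed; the result is identical to the streaming path.
#'
#' @param mixture an [RVMMixture-class]
#' @param rc run covariances from [runCovariances()]
#' @return list with `probs` (n x nClasses mixture probabilities), `pred`,
#'   `probTrue` (probability assigned to the true label), `weights`
#'   (n x m), `info` (the rc info), `accuracy`, `qcm`
#' @export
mixtureReplay <- function(mixture, rc) {
  subs <- mixture@submodels
  m <- length(subs)
  n <- length(rc$covs)
  nc <- subs[[1]]@rvm@nClasses
  Pall <- array(0, c(n, nc, m))
  Dall <- matrix(0, n, m)
  for (i in seq_len(m)) {
    proj <- lapply(rc$covs, projectCovariance, filter = subs[[i]]@filter)
    Dall[, i] <- vapply(proj, riemannDistance, numeric(1), S2 = subs[[i]]@mu)
    tf <- tangentFeatures(proj, ref = subs[[i]]@mu)
    Pall[, , i] <- predictProba(subs[[i]]@rvm, tf$features)
  }
  priorVec <- vapply(subs, function(s) s@prior, numeric(1))
  probs <- matrix(0, n, nc)
  weights <- matrix(0, n, m)
  trialCol <- rc$info$trial
  for (tr in unique(trialCol)) {
    idx <- which(trialCol == tr)
    dbar <- rep(NA_real_, m)
    for (j in seq_along(idx)) {
      r <- idx[j]
      dbar <- if (j == 1) Dall[r, ] else (dbar * (j - 1) + Dall[r, ]) / j
      w <- .mixtureWeights(priorVec, dbar)
      weights[r, ] <- w
      probs[r, ] <- matrix(Pall[r, , ], ncol = m) %*% w
    }
  }
  pred <- apply(probs, 1, which.max)
  Q <- confusionMatrix(rc$info$label, pred, nClasses = nc)
  list(probs = probs, pred = pred,
       probTrue = probs[cbind(seq_len(n), rc$info$label)],
       weights = weights, info = rc$info,
       accuracy = mean(pred == rc$info$label), qcm = confusionQuality(Q))
}

#' Replay a run with protocol feedback
#'
#' Replays one run segment-by-segment and logs the feedback events the
#' subject would have seen. Modes: `"sham"` (calibration run: the displayed
#' motion is correct with probability 0.8 and random otherwise, independent
#' of any classifier), `"constrained"` (the swarm advances only when the
#' prediction is correct), `"full"` (the feedback follows the raw argmax
#' prediction stream).
#'
#' @param mixture an [RVMMixture-class], or NULL in sham mode
#' @param session an [EEGSession-class]
#' @param run run index to replay
#' @param mode feedback mode
#' @param seed seed for the sham randomization
#' @param window,step segmentation parameters (s)
#' @return data.frame log with one row per segment: trial, segment, label,
#'   pred, probTrue, maxProb, feedbackCorrect, feedbackClass
#' @export
runProtocol <- function(mixture, session, run,
                        mode = c("sham", "constrained", "full"), seed = 1L,
                        window = 2, step = 0.25) {
  mode <- match.arg(mode)
  rc <- runCovariances(session, run, window = window, step = step)
  n <- length(rc$covs)
  if (!is.null(mixture)) {
    rep <- mixtureReplay(mixture, rc)
    pred <- rep$pred
    probTrue <- rep$probTrue
    maxProb <- apply(rep$probs, 1, max)
  } else {
    if (mode != "sham") stop("a mixture is required outside sham mode")
    pred <- rep(NA_integer_, n)
    probTrue <- rep(NA_real_, n)
    maxProb <- rep(NA_real_, n)
  }
  lab <- rc$info$label
  if (mode == "sham") {
    set.seed(seed)
    correct <- stats::runif(n) < 0.8
    fbClass <- ifelse(correct, lab,
                      1L + (lab + sample(0:2, n, replace = TRUE)) %% 4L)
  } else if (mode == "constrained") {
    correct <- pred == lab
    fbClass <- ifelse(correct, lab, NA_integer_)   # swarm stays still
  } else {
    fbClass <- pred
    correct <- pred == lab
  }
  data.frame(run = run, trial = rc$info$trial, segment = rc$info$segment,
             label = lab, pred = pred, probTrue = probTrue,
             maxProb = maxProb, feedbackCorrect = correct,
             feedbackClass = fbClass)
}

#' Run the full between-run adaptation over a session
#'
#' Drives the whole protocol: the calibration run trains the first sub-model
#' with the heuristic k = 9; each subsequent run is first replayed through
#' the current mixture (the online predictions, logged per run), then the
#' mixture is updated: candidates trained on the previous run are
#' cross-validated on the new data to re-select k, the new run's sub-model
#' is trained (pre-filtered by the replay probabilities) and appended, and
#' all priors are refreshed.
#'
#' @param session an [EEGSession-class]
#' @param kRange candidate representative counts (default 8:12)
#' @param d CSP components (default 12)
#' @param heuristicK k of the calibration sub-model (default 9)
#' @param epsilon suppression threshold (default 0.25)
#' @param epsF pre-filter threshold (default 0.1)
#' @param maxRuns adapt over at most this many runs (default: all in the
#'   session)
#' @param window,step segmentation parameters (s)
#' @param shrinkage covariance shrinkage for segment descriptors
#' @param ... further arguments to [trainRVM()]
#' @return list with `mixture` (final [RVMMixture-class]), `history`
#'   (data.frame of per-run online accuracy/qcm and chosen k), `candidates`
#'   (the last run's candidate set)
#' @export
adaptSession <- function(session, kRange = 8:12, d = 12L, heuristicK = 9L,
                         epsilon = 0.25, epsF = 0.1, maxRuns = NULL,
                         window = 2, step = 0.25, shrinkage = 0, ...) {
  stopifnot(is(session, "EEGSession"))
  runsAvail <- sort(unique(session@info$run))
  if (!is.null(maxRuns)) runsAvail <- runsAvail[seq_len(min(maxRuns,
                                                            length(runsAvail)))]
  rc0 <- runCovariances(session, runsAvail[1], window, step, shrinkage)
  sm0 <- trainSubModel(rc0, k = heuristicK, d = d, run = runsAvail[1], ...)
  mixture <- RVMMixture(list(sm0), epsilon)
  candidatesPrev <- NULL
  history <- data.frame()
  for (r in runsAvail[-1]) {
    rc <- runCovariances(session, r, window, step, shrinkage)
    replay <- mixtureReplay(mixture, rc)
    prevSub <- mixture@submodels[[which.max(
      vapply(mixture@submodels, function(s) s@run, integer(1)))]]
    candidatesNew <- trainCandidates(
      rc, kRange = if (is.null(candidatesPrev)) heuristicK else kRange,
      d = d, filterInit = prevSub@filter, probTrue = replay$probTrue,
      epsF = epsF, run = r, ...)
    up <- updateMixture(mixture, rc, candidatesPrev, candidatesNew,
                        heuristicK = heuristicK)
    mixture <- up$mixture
    if (is.null(candidatesPrev) && length(kRange) > 1) {
      # widen the new run's candidate set for the next cross-validation
      extraK <- setdiff(kRange, vapply(candidatesNew, function(s) s@k,
                                       integer(1)))
      if (length(extraK)) {
        more <- trainCandidates(rc, kRange = extraK, d = d,
                                filterInit = prevSub@filter,
                                probTrue = replay$probTrue, epsF = epsF,
                                run = r, ...)
        candidatesNew <- c(candidatesNew, more)
      }
    }
    candidatesPrev <- candidatesNew
    history <- rbind(history, data.frame(run = r, accuracy = replay$accuracy,
                                         qcm = replay$qcm, kStar = up$kStar))
  }
  list(mixture = mixture, history = history, candidates = candidatesPrev)
}

#' Separability and instability report for one run
#'
#' Applies a `d`-component CSP (fitted on this run's own data, or a supplied
#' filter from the previous run) and reports the pairwise class
#' separability table and the per-class instability.
#'
#' @param rc run covariances from [runCovariances()]
#' @param d CSP components (default 12)
#' @param filter optional [SpatialFilter-class] to reuse (previous-run
#'   method); NULL fits one on this run (own-run method, the default)
#' @return list with `separability` (data.frame pair/value), `instability`
#'   (named integer per class), `filter`
#' @export
runReport <- function(rc, d = 12L, filter = NULL) {
  if (is.null(filter)) {
    filter <- fitSpatialFilter(rc$covs, rc$info$label, d = d)
  }
  proj <- lapply(rc$covs, projectCovariance, filter = filter)
  byClass <- lapply(1:4, function(c) proj[rc$info$label == c])
  pairs <- utils::combn(4, 2)
  sep <- data.frame(
    pair = apply(pairs, 2, paste, collapse = "-"),
    value = apply(pairs, 2, function(p) {
      classSeparability(byClass[[p[1]]], byClass[[p[2]]])
    }))
  inst <- vapply(1:4, function(c) classInstability(byClass[[c]]), integer(1))
  names(inst) <- paste0("C", 1:4)
  list(separability = sep, instability = inst, filter = filter)
}
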