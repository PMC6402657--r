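# Seeded generator of synthetic multi-channel, four-class sessions whose
# discriminative structure lives entirely in the spatial covariance: class
# prototypes on the SPD manifold, trial-level tangent dispersion, run-to-run
# drift, contraction of the dispersion with feedback (exploitation), and
# optional implanted outlier spans.

#' Construct a generator configuration
#'
#' Defaults reproduce the acquisition protocol the pipeline targets: 60
#' channels at 256 Hz, 7 runs of 40 ten-second trials (10 per class),
#' segmented into 2 s windows every 0.25 s (33 segments/trial, 1320
#' labeled segments per run). The free simulation magnitudes default to a
#' mid-performing user: prototype separation 0.8, trial dispersion 0.4,
#' run-to-run drift 0.15, exploitation factor 0.9, outlier probability 0.1.
#'
#' @param nChannels,rate,nRuns,trialsPerClass,trialSec,windowSec,stepSec
#'   protocol constants, see [GeneratorConfig-class]
#' @param separation,tau,drift,gamma,pOut,seed simulation magnitudes, see
#'   [GeneratorConfig-class]
#' @return a [GeneratorConfig-class]
#' @export
generatorConfig <- function(nChannels = 60L, rate = 256, nRuns = 7L,
                            trialsPerClass = 10L, trialSec = 10,
                            windowSec = 2, stepSec = 0.25,
                            separation = 0.8, tau = 0.4, drift = 0.15,
                            gamma = 0.9, pOut = 0.1, seed = 1L) {
  new("GeneratorConfig", nChannels = as.integer(nChannels),
      rate = as.numeric(rate), nRuns = as.integer(nRuns),
      trialsPerClass = as.integer(trialsPerClass),
      trialSec = as.numeric(trialSec), windowSec = as.numeric(windowSec),
      stepSec = as.numeric(stepSec), separation = as.numeric(separation),
      tau = as.numeric(tau), drift = as.numeric(drift),
      gamma = as.numeric(gamma), pOut = as.numeric(pOut),
      seed = as.integer(seed))
}

# deterministic per-trial seed derived from the session seed (kept < 2^31)
.deriveSeed <- function(seed, run, trial, salt = 0L) {
  as.integer((as.numeric(seed) * 2654435 + run * 97003 + trial * 7919 +
                salt * 131) %% 2147483647)
}

# random symmetric matrix with unit Frobenius norm (tangent direction in
# whitened coordinates)
.randomUnitTangent <- function(d) {
  M <- matrix(stats::rnorm(d * d), d)
  M <- (M + t(M)) / 2
  M / sqrt(sum(M^2))
}

# orthonormalize symmetric matrices under the Frobenius inner product
.gramSchmidtSym <- function(mats) {
  out <- list()
  for (M in mats) {
    for (B in out) M <- M - sum(M * B) * B
    nrm <- sqrt(sum(M^2))
    if (nrm < 1e-10) stop("degenerate tangent directions")
    out <- c(out, list(M / nrm))
  }
  out
}

# AR(1)-structured base covariance: correlation decaying with channel index
# distance, overall scale in the tens of microvolts squared typical of
# band-passed EEG
.baseCovariance <- function(d, rho = 0.5, scale = 10) {
  scale * rho^abs(outer(seq_len(d), seq_len(d), `-`))
}

#' Class prototype covariances of the generator
#'
#' Places the four class prototypes at geodesic magnitude
#' `separation` from a common AR(1) base covariance, along four fixed
#' orthonormal tangent directions drawn deterministically from the seed.
#' With `separation = 0` all prototypes equal the base covariance.
#'
#' @param config a [GeneratorConfig-class]
#' @return list with `base` (SPD matrix), `prototypes` (list of 4 SPD
#'   matrices) and `directions` (the orthonormal tangent directions)
#' @export
makePrototypes <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  d <- config@nChannels
  C0 <- .baseCovariance(d)
  set.seed(.deriveSeed(config@seed, 0L, 0L, salt = 1L))
  dirs <- .gramSchmidtSym(replicate(4, .randomUnitTangent(d),
                                    simplify = FALSE))
  protos <- lapply(dirs, function(U) {
    .expMapMat(config@separation * U, C0)
  })
  list(base = C0, prototypes = protos, directions = dirs)
}

#' Generate one synthetic trial
#'
#' The trial mean covariance is `exp_map(tau * V, prototype)` with a random
#' unit tangent direction `V`. The 10 s series is zero-mean Gaussian,
#' generated in short blocks whose covariance fluctuates around the trial
#' mean in two ways that emulate real within-trial EEG variability:
#'
#' * a low-rank baseline power fluctuation (an AR(1) scalar modulating the
#'   overall scale along the identity tangent direction, magnitude
#'   `scaleSD`, demeaned within the trial) — always present, independent of
#'   the user's state;
#' * an exploratory covariance random walk in random (high-rank) tangent
#'   directions whose magnitude scales with `tau` (factor `exploreWithin`)
#'   — the within-trial counterpart of trial-level exploration, vanishing
#'   under full exploitation.
#'
#' With probability `pOut` one random window-length span is replaced by
#' samples from a far-off covariance (a distraction/outlier), recorded in
#' the ground truth.
#'
#' @param prototype SPD class prototype
#' @param tau trial-level tangent dispersion
#' @param pOut probability of an implanted outlier span
#' @param seed integer seed (fixes the trial bit-exactly)
#' @param nSamples samples in the trial
#' @param rate sampling rate (Hz)
#' @param windowSec outlier span length (s)
#' @param outlierMagnitude tangent magnitude of the outlier covariance
#' @param blockSec covariance-update block length (s)
#' @param scaleSD magnitude of the baseline power fluctuation
#' @param exploreWithin within-trial exploration magnitude per unit tau
#' @return list with `samples` (channels x nSamples matrix), `trialMean`
#'   (SPD), `outlierSpan` (c(start, end) in samples, or NULL)
#' @export
generateTrial <- function(prototype, tau, pOut, seed, nSamples, rate,
                          windowSec = 2, outlierMagnitude = 3,
                          blockSec = 0.25, scaleSD = 0.5,
                          exploreWithin = 2) {
  set.seed(seed)
  d <- nrow(prototype)
  V <- .randomUnitTangent(d)
  Mtrial <- .expMapMat(tau * V, prototype)
  blen <- max(1L, round(blockSec * rate))
  B <- ceiling(nSamples / blen)
  # baseline power fluctuation: AR(1), unit stationary sd, demeaned so the
  # trial's pooled covariance stays at the trial mean
  g <- numeric(B)
  e <- stats::rnorm(B)
  for (b in seq_len(B)) g[b] <- if (b == 1) e[1] else 0.8 * g[b - 1] +
      sqrt(1 - 0.64) * e[b]
  g <- g - mean(g)
  # exploratory covariance excursions: AR(1)-correlated random tangent
  # directions (high rank across blocks), demeaned likewise
  walks <- vector("list", B)
  Wc <- matrix(0, d, d)
  amp <- tau * exploreWithin
  phi <- 0.5
  Wsum <- matrix(0, d, d)
  for (b in seq_len(B)) {
    if (amp > 0) {
      innov <- amp * .randomUnitTangent(d)
      Wc <- if (b == 1) innov else phi * Wc + sqrt(1 - phi^2) * innov
    }
    walks[[b]] <- Wc
    Wsum <- Wsum + Wc
  }
  Wmean <- Wsum / B
  E <- diag(d) / sqrt(d)
  Mh <- .matPow(Mtrial, 0.5, warn = FALSE)
  X <- matrix(0, d, B * blen)
  for (b in seq_len(B)) {
    Tb <- scaleSD * g[b] * E + (walks[[b]] - Wmean)
    Ab <- Mh %*% .matPow(.matExp(Tb), 0.5, warn = FALSE)
    X[, ((b - 1) * blen + 1):(b * blen)] <-
      Ab %*% matrix(stats::rnorm(d * blen), d)
  }
  X <- X[, seq_len(nSamples), drop = FALSE]
  span <- NULL
  if (stats::runif(1) < pOut) {
    wlen <- round(windowSec * rate)
    start <- sample.int(nSamples - wlen + 1L, 1L)
    Vout <- .randomUnitTangent(d)
    Mout <- .expMapMat(outlierMagnitude * Vout, Mtrial)
    Aout <- t(chol(Mout))
    X[, start:(start + wlen - 1L)] <-
      Aout %*% matrix(stats::rnorm(d * wlen), d)
    span <- c(start, start + wlen - 1L)
  }
  list(samples = X, trialMean = Mtrial, outlierSpan = span)
}

#' Generate a full synthetic session
#'
#' Runs are generated in order: run r uses prototypes drifted from run r-1
#' by `exp_map(drift * G_c, .)` along fixed per-class directions, and trial
#' dispersion `tau * gamma^r` (exploitation: the user's repetitions tighten
#' as feedback accumulates). Labels are balanced within each run and
#' shuffled with the session seed. The returned session carries the full
#' ground truth (per-run prototypes, per-trial means, outlier spans, config).
#'
#' @param config a [GeneratorConfig-class]
#' @return an [EEGSession-class] with ground truth attached
#' @export
generateSession <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  pr <- makePrototypes(config)
  d <- config@nChannels
  nTrials <- 4L * config@trialsPerClass
  nSamples <- round(config@trialSec * config@rate)
  set.seed(.deriveSeed(config@seed, 0L, 0L, salt = 2L))
  driftDirs <- lapply(1:4, function(i) .randomUnitTangent(d))
  protos <- pr$prototypes
  trials <- list(); labels <- integer(0); runs <- integer(0)
  gtProtos <- list(); gtMeans <- list()
  gtOut <- data.frame(run = integer(0), trial = integer(0),
                      start = integer(0), end = integer(0))
  for (r in seq_len(config@nRuns) - 1L) {
    if (r > 0L && config@drift > 0) {
      protos <- lapply(1:4, function(c) {
        .expMapMat(config@drift * driftDirs[[c]], protos[[c]])
      })
    }
    gtProtos[[r + 1L]] <- protos
    tauR <- config@tau * config@gamma^r
    set.seed(.deriveSeed(config@seed, r, 0L, salt = 3L))
    lab <- sample(rep(1:4, config@trialsPerClass))
    for (j in seq_len(nTrials)) {
      tr <- generateTrial(protos[[lab[j]]], tauR, config@pOut,
                          seed = .deriveSeed(config@seed, r, j),
                          nSamples = nSamples, rate = config@rate,
                          windowSec = config@windowSec)
      trials[[length(trials) + 1L]] <- tr$samples
      gtMeans[[length(trials)]] <- tr$trialMean
      if (!is.null(tr$outlierSpan)) {
        gtOut <- rbind(gtOut, data.frame(run = r, trial = j,
                                         start = tr$outlierSpan[1],
                                         end = tr$outlierSpan[2]))
      }
    }
    labels <- c(labels, lab)
    runs <- c(runs, rep(r, nTrials))
  }
  EEGSession(trials, labels, runs, config@rate,
             groundTruth = list(prototypes = gtProtos, trialMeans = gtMeans,
                                outliers = gtOut, config = config),
             provenance = sprintf("synthetic (seed %d)", config@seed))
}

#' Segment-level outlier flags from the ground truth
#'
#' Flags every segment of a trial whose window overlaps an implanted outlier
#' span.
#'
#' @param session a generated [EEGSession-class]
#' @param run run index
#' @return logical matrix, trials (of the run) x segments
#' @export
outlierFlags <- function(session, run) {
  gt <- session@groundTruth
  if (!length(gt)) stop("session has no ground truth")
  cfg <- gt$config
  nSamples <- round(cfg@trialSec * cfg@rate)
  wlen <- round(cfg@windowSec * cfg@rate)
  slen <- round(cfg@stepSec * cfg@rate)
  starts <- seq(1L, nSamples - wlen + 1L, by = slen)
  nTrials <- sum(session@info$run == run)
  flags <- matrix(FALSE, nTrials, length(starts))
  out <- gt$outliers[gt$outliers$run == run, , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    ovl <- starts <= out$end[i] & (starts + wlen - 1L) >= out$start[i]
    flags[out$trial[i], ovl] <- TRUE
  }
  flags
}

#' One step of the feedback-responsive user model
#'
#' Emulates exploration/exploitation: after a trial whose feedback was
#' majority-correct the dispersion contracts by `gamma`; after a
#' majority-incorrect trial it inflates by `1/gamma`; a feedback regime
#' change (constrained -> full) triggers one prototype drift step along the
#' stored drift directions.
#'
#' @param state list with elements `tau`, `gamma`, `prototypes`,
#'   `driftDirs`, `driftStep`
#' @param event one of `"trial_correct"`, `"trial_incorrect"`,
#'   `"regime_change"`
#' @return the updated state
#' @export
userModelStep <- function(state, event = c("trial_correct",
                                           "trial_incorrect",
                                           "regime_change")) {
  event <- match.arg(event)
  if (event == "trial_correct") {
    state$tau <- state$tau * state$gamma
  } else if (event == "trial_incorrect") {
    state$tau <- state$tau / state$gamma
  } else {
    state$prototypes <- lapply(seq_along(state$prototypes), function(c) {
      .expMapMat(state$driftStep * state$driftDirs[[c]],
                 state$prototypes[[c]])
    })
  }
  state
}
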