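# Preprocessing of multichannel EEG: Butterworth band-pass, notch,
# polyphase resampling, and sliding-window segmentation.

.applyByChannel <- function(x, fn) {
  t(apply(x, 1, fn))
}

#' Butterworth band-pass filter
#'
#' 5th-order Butterworth band-pass (default 8-70 Hz, the band retained for
#' feature extraction), applied per channel. `mode = "zerophase"` runs the
#' filter forward-backward (offline analysis); `mode = "causal"` runs a
#' single causal pass (online replay).
#'
#' @param x channels x samples numeric matrix (microvolts)
#' @param rate sampling rate in Hz; must exceed twice the upper edge
#' @param low,high band edges in Hz
#' @param order filter order
#' @param mode `"zerophase"` or `"causal"`
#' @return filtered matrix of the same shape
#' @export
bandpassFilter <- function(x, rate, low = 8, high = 70, order = 5L,
                           mode = c("zerophase", "causal")) {
  mode <- match.arg(mode)
  if (rate <= 2 * high) stop("sampling rate too low for the requested band")
  if (!all(is.finite(x))) stop("non-finite input")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  run <- if (mode == "zerophase") {
    function(v) signal::filtfilt(bf, v)
  } else {
    function(v) as.numeric(signal::filter(bf, v))
  }
  y <- .applyByChannel(x, run)
  if (!all(is.finite(y))) stop("unstable filter output")
  dimnames(y) <- dimnames(x)
  y
}

#' Notch filter for line noise
#'
#' Second-order Butterworth band-stop around `freq` (default 60 Hz line
#' noise), applied per channel.
#'
#' @inheritParams bandpassFilter
#' @param freq center frequency to suppress (Hz)
#' @param width half stop-band width in Hz
#' @return filtered matrix of the same shape
#' @export
notchFilter <- function(x, rate, freq = 60, width = 2, mode = c("zerophase",
                                                                "causal")) {
  mode <- match.arg(mode)
  if (rate <= 2 * (freq + width)) stop("sampling rate too low for the notch")
  bf <- signal::butter(2L, c(freq - width, freq + width) / (rate / 2),
                       type = "stop")
  run <- if (mode == "zerophase") {
    function(v) signal::filtfilt(bf, v)
  } else {
    function(v) as.numeric(signal::filter(bf, v))
  }
  y <- .applyByChannel(x, run)
  if (!all(is.finite(y))) stop("unstable filter output")
  dimnames(y) <- dimnames(x)
  y
}

#' Rational resampling
#'
#' Resamples each channel by the rational factor `target/rate` (reduced; for
#' 1000 -> 256 Hz this is 32/125). Anti-aliasing and interpolation are done
#' in the Fourier domain (exact for band-limited signals); reflection
#' padding keeps the periodicity assumption away from the retained span.
#' Duration is preserved to within one output sample.
#'
#' @inheritParams bandpassFilter
#' @param target target rate in Hz (must divide rationally into `rate` within
#'   `maxDenominator`)
#' @param maxDenominator largest denominator accepted when reducing the ratio
#' @return list with `data` (resampled matrix) and `rate` (the target rate)
#' @export
resampleSignals <- function(x, rate, target = 256, maxDenominator = 1000L) {
  if (target >= rate) stop("target rate must be below the input rate")
  frac <- .rationalize(target / rate, maxDenominator)
  if (is.null(frac)) {
    stop("resampling ratio has no rational form with denominator <= ",
         maxDenominator)
  }
  p <- frac[1]; q <- frac[2]
  n <- ncol(x)
  nOut <- ceiling(n * p / q)
  npad <- if (n > 2L) min(n - 2L, 8L * q) else 0L
  y <- t(apply(x, 1, function(v) {
    vp <- if (npad > 0) {
      c(rev(v[2:(npad + 1L)]), v, rev(v[(n - npad):(n - 1L)]))
    } else v
    m2 <- round(length(vp) * p / q)
    out <- .fftResample(vp, m2)
    off <- round(npad * p / q)
    out[(off + 1L):(off + nOut)]
  }))
  list(data = y, rate = rate * p / q)
}

# Fourier-domain resampling of a real vector to length m (m < n): truncate
# the spectrum at the new Nyquist and inverse-transform.
.fftResample <- function(v, m) {
  n <- length(v)
  X <- stats::fft(v)
  Y <- complex(m)
  half <- floor(m / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half >= 1) Y[(m - half + 1):m] <- X[(n - half + 1):n]
  if (m %% 2 == 0) {
    # shared Nyquist bin: make the spectrum conjugate-symmetric
    Y[half + 1] <- Re(X[half + 1])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# best rational approximation p/q == r exactly (within 1e-12), else NULL
.rationalize <- function(r, maxDen) {
  for (q in seq_len(maxDen)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) {
      g <- .gcd(round(p), q)
      return(c(round(p) / g, q / g))
    }
  }
  NULL
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Sliding-window segmentation of a trial
#'
#' Splits a channels x samples trial into overlapping windows of `window`
#' seconds advancing by `step` seconds: `floor((duration - window)/step) + 1`
#' segments, the first starting at 0 and the last ending at the trial end.
#' A 10 s trial with 2 s windows and 0.25 s steps yields 33 segments.
#'
#' @param x channels x samples matrix
#' @param rate sampling rate (Hz)
#' @param window window length in seconds
#' @param step window step in seconds
#' @return list of channels x (window*rate) matrices
#' @export
segmentTrial <- function(x, rate, window = 2, step = 0.25) {
  wlen <- round(window * rate)
  slen <- round(step * rate)
  n <- ncol(x)
  if (wlen > n) stop("window longer than the trial")
  starts <- seq(1L, n - wlen + 1L, by = slen)
  lapply(starts, function(s) x[, s:(s + wlen - 1L), drop = FALSE])
}

#' Number of segments a trial yields
#'
#' @param duration trial duration (s)
#' @param window window length (s)
#' @param step window step (s)
#' @return integer segment count
#' @export
segmentCount <- function(duration, window = 2, step = 0.25) {
  as.integer(floor((duration - window) / step + 1e-9) + 1)
}

#' Hook for ocular-artifact removal
#'
#' Placeholder where an EOG regression/removal algorithm would run when EOG
#' reference channels are available; the default implementation is the
#' identity (no removal). Supplying a function swaps the behaviour in.
#'
#' @param x channels x samples matrix
#' @param eog optional EOG channels x samples matrix
#' @param method function of `(x, eog)` returning a cleaned matrix
#' @return cleaned matrix
#' @export
removeEOGArtifacts <- function(x, eog = NULL, method = NULL) {
  if (is.null(method)) return(x)
  method(x, eog)
}

#' Preprocess every trial of a session
#'
#' Applies, in order: optional resampling to `target` Hz, band-pass, notch.
#' Provenance strings are appended to the session.
#'
#' @param session an [EEGSession-class]
#' @param low,high band-pass edges (Hz)
#' @param notch notch center frequency (Hz), or NA to skip
#' @param target target rate (Hz), or NA to keep the native rate
#' @param mode `"zerophase"` or `"causal"` filtering
#' @return the preprocessed [EEGSession-class]
#' @export
preprocessSession <- function(session, low = 8, high = 70, notch = 60,
                              target = NA, mode = "zerophase") {
  stopifnot(is(session, "EEGSession"))
  rate <- session@rate
  trials <- session@trials
  prov <- session@provenance
  if (!is.na(target) && target < rate) {
    trials <- lapply(trials, function(x) resampleSignals(x, rate, target)$data)
    rate <- target
    prov <- c(prov, sprintf("resample->%gHz", target))
  }
  trials <- lapply(trials, function(x) {
    y <- bandpassFilter(x, rate, low, high, mode = mode)
    if (!is.na(notch) && rate > 2 * (notch + 2)) {
      y <- notchFilter(y, rate, notch, mode = mode)
    }
    y
  })
  prov <- c(prov, sprintf("bandpass %g-%gHz (%s)", low, high, mode))
  if (!is.na(notch) && rate > 2 * (notch + 2)) {
    prov <- c(prov, sprintf("notch %gHz", notch))
  }
  initialize(session, trials = trials, rate = rate, provenance = prov)
}

#' Per-segment covariance descriptors of one run
#'
#' Segments every trial of the given run and computes the full-channel
#' covariance descriptor of each segment. Downstream spatial filtering uses
#' the congruence `W' C W`, so covariances are computed once per segment at
#' full channel count and projected as needed.
#'
#' @param session an [EEGSession-class]
#' @param run run index to extract (matching `trialInfo(session)$run`)
#' @param window,step segmentation window and step (s)
#' @param shrinkage covariance shrinkage passed to [covDescriptor()]
#' @return list with `covs` (list of SPD matrices) and `info` (data.frame
#'   with label, trial, segment columns)
#' @export
runCovariances <- function(session, run, window = 2, step = 0.25,
                           shrinkage = 0) {
  stopifnot(is(session, "EEGSession"))
  sel <- which(session@info$run == run)
  if (!length(sel)) stop("no trials in run ", run)
  covs <- list()
  lab <- integer(0); tri <- integer(0); seg <- integer(0)
  for (i in sel) {
    segs <- segmentTrial(session@trials[[i]], session@rate, window, step)
    cv <- lapply(segs, covDescriptor, shrinkage = shrinkage)
    covs <- c(covs, cv)
    lab <- c(lab, rep(session@info$label[i], length(cv)))
    tri <- c(tri, rep(session@info$trial[i], length(cv)))
    seg <- c(seg, seq_along(cv))
  }
  list(covs = covs,
       info = data.frame(label = lab, trial = tri, segment = seg))
}
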