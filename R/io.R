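# Ingestion: EDF and BrainVision readers, epoching by event markers, the
# internal session format, and CSV export of segment-level predictions.

#' Construct an EEG session container
#'
#' @param trials list of channels x samples numeric matrices
#' @param labels integer class labels (1..4), one per trial
#' @param runs integer run index per trial (0-based; run 0 is the
#'   calibration run)
#' @param rate sampling rate (Hz)
#' @param groundTruth optional generator ground truth
#' @param provenance character log of processing applied so far
#' @return an [EEGSession-class]
#' @export
EEGSession <- function(trials, labels, runs, rate, groundTruth = list(),
                       provenance = character(0)) {
  labels <- as.integer(labels)
  runs <- as.integer(runs)
  info <- data.frame(label = labels, run = runs,
                     trial = stats::ave(runs, runs, FUN = seq_along))
  new("EEGSession", trials = trials, info = info, rate = as.numeric(rate),
      groundTruth = groundTruth, provenance = provenance)
}

.readChars <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

#' Read a (plain) EDF recording
#'
#' Minimal European Data Format reader: parses the fixed-offset ASCII header
#' and the 16-bit little-endian data records, returning physically scaled
#' signals. Handles equal-rate signal channels (the common continuous-EEG
#' case); EDF+ annotation channels are skipped.
#'
#' @param path path to an .edf file
#' @return list with `data` (channels x samples matrix, physical units),
#'   `rate` (Hz), `channels` (labels)
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .readChars(con, 8)                       # version
  .readChars(con, 80); .readChars(con, 80) # patient, recording
  .readChars(con, 8); .readChars(con, 8)   # date, time
  as.integer(.readChars(con, 8))           # header bytes
  .readChars(con, 44)                      # reserved
  ndr <- as.integer(.readChars(con, 8))
  dur <- as.numeric(.readChars(con, 8))
  ns <- as.integer(.readChars(con, 4))
  labels <- vapply(seq_len(ns), function(i) .readChars(con, 16), character(1))
  for (i in seq_len(ns)) .readChars(con, 80)   # transducer
  for (i in seq_len(ns)) .readChars(con, 8)    # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(.readChars(con, 8)),
                    numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(.readChars(con, 8)),
                    numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(.readChars(con, 8)),
                   numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(.readChars(con, 8)),
                   numeric(1))
  for (i in seq_len(ns)) .readChars(con, 80)   # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(.readChars(con, 8)),
                integer(1))
  for (i in seq_len(ns)) .readChars(con, 32)   # reserved
  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (length(unique(spr[keep])) != 1) {
    stop("mixed per-channel sampling rates are not supported")
  }
  out <- matrix(0, sum(keep), ndr * spr[keep][1])
  rowOf <- cumsum(keep)
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                      endian = "little")
      if (keep[i]) {
        scale <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
        out[rowOf[i], ((r - 1) * spr[i] + 1):(r * spr[i])] <-
          (vals - digMin[i]) * scale + physMin[i]
      }
    }
  }
  rownames(out) <- labels[keep]
  list(data = out, rate = spr[keep][1] / dur, channels = labels[keep])
}

#' Write a (plain) EDF recording
#'
#' Companion writer to [readEDF()]: physically scaled signals are quantized
#' to 16-bit with the given physical range. One data record per second.
#'
#' @param data channels x samples matrix
#' @param rate sampling rate (Hz); `ncol(data)` must be a multiple of it
#' @param path output path
#' @param physRange symmetric physical range for quantization
#' @return `path`, invisibly
#' @export
writeEDF <- function(data, rate, path, physRange = 3276.7) {
  ns <- nrow(data)
  if (ncol(data) %% rate != 0) stop("whole seconds of data required")
  ndr <- ncol(data) / rate
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, n) {
    s <- substr(as.character(x), 1, n)
    writeChar(formatC(s, width = -n), con, eos = NULL)
  }
  pad("0", 8); pad("local patient", 80); pad("local recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 + ns * 256, 8); pad("", 44); pad(ndr, 8); pad(1, 8); pad(ns, 4)
  labs <- rownames(data)
  if (is.null(labs)) labs <- sprintf("Ch%d", seq_len(ns))
  for (l in labs) pad(l, 16)
  for (i in seq_len(ns)) pad("AgAgCl", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(-physRange, 8)
  for (i in seq_len(ns)) pad(physRange, 8)
  for (i in seq_len(ns)) pad(-32767, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(rate, 8)
  for (i in seq_len(ns)) pad("", 32)
  dig <- round(data / physRange * 32767)
  dig[dig > 32767] <- 32767; dig[dig < -32767] <- -32767
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      writeBin(as.integer(dig[i, ((r - 1) * rate + 1):(r * rate)]),
               con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

.parseIni <- function(lines) {
  sec <- NULL
  out <- list()
  for (l in lines) {
    l <- sub(";.*$", "", l)
    l <- trimws(l)
    if (!nzchar(l)) next
    if (grepl("^\\[.*\\]$", l)) {
      sec <- gsub("^\\[|\\]$", "", l)
      out[[sec]] <- list()
    } else if (grepl("=", l) && !is.null(sec)) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Parses the .vhdr header, the .vmrk marker file and the data file.
#' Supported data layouts: binary INT_16 / IEEE_FLOAT_32 (multiplexed or
#' vectorized) and ASCII (vectorized). Stimulus markers of the form
#' `S<space><n>` are parsed into numeric codes.
#'
#' @param vhdr path to the .vhdr header file
#' @return list with `data` (channels x samples, physical units), `rate`
#'   (Hz), `channels` (labels) and `markers` (data.frame with type,
#'   description, code, position)
#' @export
readBrainVision <- function(vhdr) {
  hdr <- .parseIni(readLines(vhdr, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  dataFile <- file.path(dirname(vhdr), ci$DataFile)
  nCh <- as.integer(ci$NumberOfChannels)
  rate <- 1e6 / as.numeric(ci$SamplingInterval)
  orientation <- toupper(ifelse(is.null(ci$DataOrientation), "MULTIPLEXED",
                                ci$DataOrientation))
  fmt <- toupper(ci$DataFormat)
  chInfo <- hdr[["Channel Infos"]]
  labs <- character(nCh); res <- rep(1, nCh)
  for (i in seq_len(nCh)) {
    parts <- strsplit(chInfo[[sprintf("Ch%d", i)]], ",")[[1]]
    labs[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(trimws(parts[3]))) {
      res[i] <- as.numeric(parts[3])
    }
  }
  if (fmt == "BINARY") {
    bi <- hdr[["Binary Infos"]]
    bfmt <- toupper(bi$BinaryFormat)
    sz <- file.info(dataFile)$size
    if (bfmt == "INT_16") {
      raw <- readBin(dataFile, "integer", n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
    } else if (bfmt == "IEEE_FLOAT_32") {
      raw <- readBin(dataFile, "numeric", n = sz / 4, size = 4,
                     endian = "little")
    } else stop("unsupported BinaryFormat: ", bfmt)
    nS <- length(raw) / nCh
    data <- if (orientation == "MULTIPLEXED") {
      matrix(raw, nrow = nCh)
    } else {
      t(matrix(raw, ncol = nCh))
    }
    data <- data * res
  } else if (fmt == "ASCII") {
    ai <- hdr[["ASCII Infos"]]
    skip <- if (!is.null(ai$SkipLines)) as.integer(ai$SkipLines) else 0L
    lines <- readLines(dataFile, warn = FALSE)
    if (skip > 0) lines <- lines[-seq_len(skip)]
    if (orientation != "VECTORIZED") {
      stop("ASCII data must be VECTORIZED")
    }
    data <- t(vapply(seq_len(nCh), function(i) {
      as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    }, as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]]))) * res
  } else stop("unsupported DataFormat: ", fmt)
  rownames(data) <- labs
  markers <- data.frame(type = character(0), description = character(0),
                        code = integer(0), position = integer(0))
  if (!is.null(ci$MarkerFile)) {
    mf <- file.path(dirname(vhdr), ci$MarkerFile)
    if (file.exists(mf)) {
      mk <- .parseIni(readLines(mf, warn = FALSE))[["Marker Infos"]]
      rows <- lapply(mk, function(v) strsplit(v, ",")[[1]])
      markers <- data.frame(
        type = vapply(rows, `[`, character(1), 1),
        description = vapply(rows, `[`, character(1), 2),
        position = vapply(rows, function(r) as.integer(r[3]), integer(1))
      )
      markers$code <- suppressWarnings(
        as.integer(sub("^S\\s*", "", markers$description)))
    }
  }
  list(data = data, rate = rate, channels = labs, markers = markers)
}

#' Epoch a continuous recording into labeled trials
#'
#' Cuts fixed-length trials from a continuous recording at event-marker
#' positions; the marker code is the class label.
#'
#' @param data channels x samples matrix
#' @param rate sampling rate (Hz)
#' @param events data.frame with columns `position` (1-based sample index)
#'   and `code` (class label 1..4); rows with codes outside 1..4 are ignored
#' @param trialSec trial duration (s)
#' @param runs optional run index per retained event (default all 0)
#' @return an [EEGSession-class]
#' @export
epochSession <- function(data, rate, events, trialSec = 10, runs = NULL) {
  keep <- which(events$code %in% 1:4 &
                  events$position + round(trialSec * rate) - 1 <= ncol(data))
  events <- events[keep, , drop = FALSE]
  if (!nrow(events)) stop("no usable events")
  if (is.null(runs)) runs <- rep(0L, nrow(events))
  n <- round(trialSec * rate)
  trials <- lapply(seq_len(nrow(events)), function(i) {
    s <- events$position[i]
    data[, s:(s + n - 1), drop = FALSE]
  })
  EEGSession(trials, events$code, runs, rate,
             provenance = "epoched from continuous recording")
}

#' Read / write the internal session format
#'
#' One file per session, holding the raw trials, labels, run indices,
#' preprocessing provenance and any generator ground truth (including its
#' seed). The container is native R serialization (version 3), which
#' round-trips bit-exactly.
#'
#' @param session an [EEGSession-class]
#' @param path file path
#' @return `readSession` returns the [EEGSession-class]; `writeSession`
#'   returns `path` invisibly
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "EEGSession"))
  payload <- list(format = "riemix-session", version = 1L,
                  trials = session@trials, info = session@info,
                  rate = session@rate, groundTruth = session@groundTruth,
                  provenance = session@provenance)
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "riemix-session")) {
    stop("not a session file: ", path)
  }
  new("EEGSession", trials = payload$trials, info = payload$info,
      rate = payload$rate, groundTruth = payload$groundTruth,
      provenance = payload$provenance)
}

#' Export segment-level predictions as CSV
#'
#' @param predictions data.frame of per-segment predictions (as produced by
#'   [runProtocol()])
#' @param path output path
#' @return `path`, invisibly
#' @export
exportPredictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
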