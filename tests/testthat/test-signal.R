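# Preprocessing and ingestion: filters, resampling, segmentation, readers,
# session format.

test_that("band-pass keeps the mid-band and rejects band edges", {
  rate <- 256
  t <- seq(0, 4, by = 1 / rate)
  mid <- 300:700   # away from edge transients
  y20 <- bandpassFilter(matrix(sin(2 * pi * 20 * t), 1), rate)
  expect_lt(abs(max(abs(y20[mid])) - 1), 0.05)
  y4 <- bandpassFilter(matrix(sin(2 * pi * 4 * t), 1), rate)
  expect_lt(20 * log10(max(abs(y4[mid]))), -20)
  dc <- bandpassFilter(matrix(1, 1, length(t)), rate)
  expect_lt(max(abs(dc[mid])), 1e-3)
  expect_error(bandpassFilter(matrix(0, 1, 100), rate = 100), "too low")
  # causal mode also suppresses out-of-band content
  y4c <- bandpassFilter(matrix(sin(2 * pi * 4 * t), 1), rate,
                        mode = "causal")
  expect_lt(max(abs(y4c[mid])), 0.2)
})

test_that("notch removes line noise and passes neighbours", {
  rate <- 256
  t <- seq(0, 4, by = 1 / rate)
  mid <- 300:700
  y60 <- notchFilter(matrix(sin(2 * pi * 60 * t), 1), rate)
  expect_lt(20 * log10(max(abs(y60[mid]))), -20)
  y30 <- notchFilter(matrix(sin(2 * pi * 30 * t), 1), rate)
  expect_lt(abs(max(abs(y30[mid])) - 1), 0.05)
  z <- notchFilter(matrix(0, 2, length(t)), rate)
  expect_equal(max(abs(z)), 0)
})

test_that("rational resampling preserves content and duration", {
  rate <- 1000
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  rs <- resampleSignals(matrix(sin(2 * pi * 10 * t), 1), rate, 256)
  expect_equal(ncol(rs$data), 2560)
  expect_equal(rs$rate, 256)
  ref <- sin(2 * pi * 10 * seq(0, by = 1 / 256, length.out = 2560))
  expect_gt(cor(as.numeric(rs$data), ref), 0.999)
  cc <- resampleSignals(matrix(2.5, 1, 1000), 1000, 256)
  expect_equal(as.numeric(cc$data), rep(2.5, 256), tolerance = 1e-6)
  expect_error(resampleSignals(matrix(0, 1, 100), 100, 200), "below")
})

test_that("segmentation yields the protocol counts", {
  expect_equal(segmentCount(10, 2, 0.25), 33L)
  expect_equal(segmentCount(2, 2, 0.25), 1L)
  x <- matrix(rnorm(4 * 2560), 4)
  segs <- segmentTrial(x, 256)
  expect_length(segs, 33)
  expect_true(all(vapply(segs, ncol, integer(1)) == 512))
  # coverage: first window starts at the first sample, last ends at the end
  expect_identical(segs[[1]], x[, 1:512])
  expect_identical(segs[[33]], x[, 2049:2560])
  expect_error(segmentTrial(matrix(0, 2, 100), 256), "window")
})

test_that("a forty-trial run yields 1320 labeled segments, 330 per class", {
  s <- generateSession(generatorConfig(nChannels = 4L, rate = 32,
                                       nRuns = 1L, trialsPerClass = 10L,
                                       separation = 0, tau = 0, pOut = 0,
                                       seed = 1L))
  rc <- runCovariances(s, 0)
  expect_length(rc$covs, 1320)
  expect_equal(as.numeric(table(rc$info$label)), rep(330, 4))
})

test_that("preprocessing is per-channel and order-independent across
           channels", {
  set.seed(13)
  x <- matrix(rnorm(3 * 512), 3)
  y <- bandpassFilter(x, 256)
  yswap <- bandpassFilter(x[c(2, 1, 3), ], 256)
  expect_equal(y[c(2, 1, 3), ], yswap, tolerance = 1e-12)
})

test_that("EDF files round-trip through the writer and reader", {
  set.seed(14)
  x <- matrix(rnorm(3 * 512, sd = 20), 3)
  rownames(x) <- c("C3", "C4", "Cz")
  path <- tempfile(fileext = ".edf")
  writeEDF(x, rate = 256, path)
  back <- readEDF(path)
  expect_equal(back$rate, 256)
  expect_equal(back$channels, c("C3", "C4", "Cz"))
  # 16-bit quantization of a +-3276.7 range: resolution 0.1
  expect_lt(max(abs(back$data - x)), 0.11)
})

test_that("BrainVision ASCII recordings are parsed with markers", {
  dir <- tempfile(); dir.create(dir)
  set.seed(15)
  n <- 200
  data <- matrix(round(rnorm(2 * n), 3), 2)
  writeLines(c("[Common Infos]", "DataFile=rec.dat", "MarkerFile=rec.vmrk",
               "DataFormat=ASCII", "DataOrientation=VECTORIZED",
               "NumberOfChannels=2", "SamplingInterval=15625",
               "[ASCII Infos]", "SkipLines=0",
               "[Channel Infos]", "Ch1=Fz,,1", "Ch2=Pz,,1"),
             file.path(dir, "rec.vhdr"))
  writeLines(apply(data, 1, paste, collapse = " "),
             file.path(dir, "rec.dat"))
  writeLines(c("[Marker Infos]",
               "Mk1=Stimulus,S  2,11,1,0",
               "Mk2=Stimulus,S  4,101,1,0"),
             file.path(dir, "rec.vmrk"))
  bv <- readBrainVision(file.path(dir, "rec.vhdr"))
  expect_equal(bv$rate, 64)
  expect_equal(bv$channels, c("Fz", "Pz"))
  expect_equal(unname(bv$data), data, tolerance = 1e-9)
  expect_equal(bv$markers$code, c(2L, 4L))
  sess <- epochSession(bv$data, bv$rate, bv$markers, trialSec = 1)
  expect_equal(trialInfo(sess)$label, c(2L, 4L))
  expect_equal(ncol(trialData(sess)[[1]]), 64)
})

test_that("the internal session format round-trips bit-exactly", {
  s <- smallSession()
  path <- tempfile(fileext = ".rds")
  writeSession(s, path)
  back <- readSession(path)
  expect_identical(trialData(back), trialData(s))
  expect_identical(trialInfo(back), trialInfo(s))
  expect_identical(samplingRate(back), samplingRate(s))
  suppressWarnings(
    expect_error(readSession(tempfile()), "cannot open|not a session"))
})

test_that("EOG hook defaults to the identity", {
  x <- matrix(rnorm(20), 2)
  expect_identical(removeEOGArtifacts(x), x)
  expect_equal(removeEOGArtifacts(x, method = function(x, eog) x * 0),
               x * 0)
})
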