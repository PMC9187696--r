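test_that("window geometry: 205 samples at 256 Hz centered on the stimulus sample", {
  fs <- 256
  data <- matrix(0, nrow = 2, ncol = 3 * fs)
  data[1, 257] <- 99 # 0-based sample 256 = round(1.0 * fs)
  rec <- Recording(data, fs, channelRegions = c("a", "a"))
  arr <- segmentWindows(rec, MarkerTrack(1.0, "note_onset"))
  expect_equal(dim(arr@windows), c(1, 205, 2))
  expect_equal(length(arr@relTime), 205)
  # stimulus sample sits after the 51 pre-stimulus samples
  expect_equal(arr@relTime[52], 0)
  expect_equal(arr@windows[1, 52, 1], 99)
  expect_equal(range(arr@relTime) * 1000, c(-51, 153) / fs * 1000)
})

test_that("markers whose windows leave the recording are dropped and counted", {
  rec <- Recording(matrix(0, 2, 512), 256, channelRegions = c("a", "a"))
  arr <- segmentWindows(rec, MarkerTrack(c(0.05, 1.0, 1.95), "note_onset"))
  expect_equal(nWindows(arr), 1)
  expect_equal(attr(arr, "nDropped"), 2)
  expect_error(
    segmentWindows(rec, MarkerTrack(0.01, "note_onset")),
    "no marker"
  )
})

test_that("reference windows on a sparse schedule are disjoint from onsets and each other", {
  fs <- 256
  rec <- Recording(matrix(rnorm(2 * 60 * fs), 2), fs, channelRegions = c("a", "a"))
  onsets <- MarkerTrack(seq(5, 55, by = 5), "note_onset")
  cfg <- segmentationConfig(nReference = 10, seed = 42)
  ref <- sampleReferenceWindows(rec, onsets, cfg)
  expect_equal(nWindows(ref), 10)
  expect_equal(attr(ref, "overlapFracUsed"), 0)
  winLen <- 204 / fs
  centers <- ref@sourceTimes
  for (tc in centers) {
    expect_gte(min(abs(tc - markerTimes(onsets))), winLen - 1e-6)
  }
  d <- abs(outer(centers, centers, "-"))
  expect_gte(min(d[upper.tri(d)]), winLen - 1e-6)
})

test_that("reference sampling relaxes stepwise under a dense schedule and reports it", {
  fs <- 256
  rec <- Recording(matrix(rnorm(2 * 60 * fs), 2), fs, channelRegions = c("a", "a"))
  dense <- MarkerTrack(seq(0.5, 59, by = 0.3), "note_onset")
  expect_message(
    ref <- sampleReferenceWindows(rec, dense, segmentationConfig(nReference = 20, seed = 1)),
    "relaxing"
  )
  expect_equal(nWindows(ref), 20)
  expect_gt(attr(ref, "overlapFracUsed"), 0)
  expect_error(
    suppressMessages(sampleReferenceWindows(
      rec, dense, segmentationConfig(nReference = 20, maxRelaxFrac = 0, seed = 1)
    )),
    "reference window"
  )
})

test_that("region averaging is the channel mean within each subregion", {
  sess <- generateSession(smallSessionSpec(4, durationS = 10))
  pp <- preprocessRecording(sess$recording)
  arr <- segmentWindows(pp, sess$phraseBoundaries)
  sets <- averageByRegion(arr)
  expect_named(sets, c("superior_temporal", "middle_temporal"))
  sel <- which(arr@channelRegions == "middle_temporal")
  manual <- apply(arr@windows[, , sel, drop = FALSE], c(1, 2), mean)
  expect_equal(unname(sets$middle_temporal@windows), unname(manual))
  expect_message(
    averageByRegion(arr, regions = c("superior_temporal", "insular")),
    "no channels"
  )
})

test_that("bootstrap resampling yields the requested count, reproducibly", {
  ws <- windowSet(matrix(rnorm(5 * 205), nrow = 5))
  r1 <- resampleWindows(ws, 200, seed = 3)
  r2 <- resampleWindows(ws, 200, seed = 3)
  expect_equal(nWindows(r1), 200)
  expect_identical(r1@windows, r2@windows)
  idx <- attr(r1, "sourceIndices")
  expect_true(all(idx >= 1 & idx <= 5))
  expect_equal(r1@windows, ws@windows[idx, ])
  expect_error(resampleWindows(windowSet(matrix(0, 0, 205)), 200), "empty")
})
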