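test_that("template matching recovers noise-free injected spikes exactly", {
  fs <- 256
  tpl <- defaultIedTemplate(fs)
  L <- length(tpl@waveform)
  x <- numeric(20 * fs)
  centers <- c(3, 7.5, 12, 18)
  for (tt in centers) {
    s0 <- round(tt * fs) - floor(L / 2)
    x[(s0 + 1):(s0 + L)] <- x[(s0 + 1):(s0 + L)] + 40 * tpl@waveform
  }
  set.seed(8)
  rec <- Recording(rbind(x, rnorm(length(x))), fs,
                   channelRegions = c("a", "a"))
  det <- detectIeds(rec, tpl, rThreshold = 0.8)
  hits <- det[det$channel == "ch1", ]
  expect_equal(nrow(hits), length(centers))
  expect_lt(max(abs(sort(hits$time_s) - centers)), 2 / fs)
  expect_true(all(hits$score > 0.99))
})

test_that("detections closer than one template length merge, keeping the higher score", {
  fs <- 256
  tpl <- IedTemplate(sin(seq(0, pi, length.out = 65)), fs)
  x <- numeric(5 * fs)
  # two overlapping copies, the second scaled (same shape, same r) -- the
  # correlation series then has twin peaks within one template length
  s0 <- 2 * fs
  x[(s0 + 1):(s0 + 65)] <- x[(s0 + 1):(s0 + 65)] + tpl@waveform
  x[(s0 + 21):(s0 + 85)] <- x[(s0 + 21):(s0 + 85)] + 0.6 * tpl@waveform
  rec <- Recording(matrix(x, 1), fs)
  det <- detectIeds(rec, tpl, rThreshold = 0.5)
  expect_equal(nrow(det), 1)
})

test_that("matching is one-sided by default; twoSided finds inverted spikes", {
  fs <- 256
  tpl <- defaultIedTemplate(fs)
  L <- length(tpl@waveform)
  x <- numeric(10 * fs)
  s0 <- 5 * fs
  x[(s0 + 1):(s0 + L)] <- -30 * tpl@waveform
  rec <- Recording(matrix(x, 1), fs)
  expect_equal(nrow(detectIeds(rec, tpl, rThreshold = 0.8)), 0)
  det2 <- detectIeds(rec, tpl, rThreshold = 0.8, twoSided = TRUE)
  expect_equal(nrow(det2), 1)
  expect_lt(det2$score[1], 0)
})

test_that("window rejection discards exactly the windows intersecting a detection", {
  fs <- 256
  rec <- Recording(matrix(rnorm(2 * 20 * fs), 2), fs, channelRegions = c("a", "a"))
  arr <- segmentWindows(rec, MarkerTrack(c(2, 5, 8, 11), "note_onset"))
  det <- data.frame(
    channel = "ch1", time_s = c(5.1, 10.5), score = 0.9, template = "t"
  )
  out <- rejectWindows(arr, det, templateDurationS = 0.25)
  # window spans t +/- [-0.199, 0.598]; detection extent +/- 0.125
  # 5.1 hits the window at 5; 10.5 + 0.125 = 10.625 < 11 - 0.199 -> no hit
  expect_equal(out$nRejected, 1)
  expect_equal(out$windows@sourceTimes, c(2, 8, 11))
  expect_error(
    rejectWindows(arr, data.frame(channel = "ch1", time_s = c(2, 5, 8, 11),
                                  score = 1, template = "t")),
    "all 4"
  )
})

test_that("template construction normalizes to unit RMS and checks rates", {
  tpl <- IedTemplate(c(1, -2, 3, 0.5), 256)
  expect_equal(sqrt(mean(tpl@waveform^2)), 1)
  rec <- Recording(matrix(rnorm(512), 1), 512)
  expect_error(detectIeds(rec, tpl), "rate")
  expect_error(IedTemplate(numeric(4), 256), "nonzero RMS")
})
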