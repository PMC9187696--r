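test_that("marker schedule is reproducible and matches the requested density", {
  spec <- smallSessionSpec(7)
  s1 <- generateMarkerSchedule(spec)
  s2 <- generateMarkerSchedule(spec)
  expect_identical(markerTimes(s1$noteOnsets), markerTimes(s2$noteOnsets))

  times <- markerTimes(s1$noteOnsets)
  expect_true(all(diff(times) > 0))
  # ~ (90 - 1.1) / 0.32 onsets; allow generous slack for IOI jitter
  expect_gt(length(times), 200)
  expect_lt(length(times), 350)
  expect_true(all(times >= 0.5 & times <= 90 - 0.6))
})

test_that("phrase boundaries are a subset of note onsets with the requested count", {
  s <- generateMarkerSchedule(smallSessionSpec(3))
  pb <- markerTimes(s$phraseBoundaries)
  expect_length(pb, 8)
  expect_true(all(pb %in% markerTimes(s$noteOnsets)))
})

test_that("ERP templates place Gaussian components at their latencies", {
  fs <- 256
  tpl <- generateErpTemplate("note_onset", fs)
  rel <- attr(tpl, "relTime")
  expect_length(tpl, floor(200 * fs / 1000) + floor(600 * fs / 1000) + 1)
  expect_equal(min(abs(rel)), 0)
  # single isolated component: value at the latency equals the amplitude
  p <- list(note_onset = data.frame(latencyMs = 300, amplitude = 2, widthMs = 50))
  tpl1 <- generateErpTemplate("note_onset", fs, p)
  rel1 <- attr(tpl1, "relTime")
  iPeak <- which.max(tpl1)
  expect_lt(abs(rel1[iPeak] - 0.3), 1 / fs + 1e-12)
  expect_equal(max(tpl1), 2, tolerance = 1e-3)
  # half maximum reached half a FWHM away from the latency
  atHalf <- approx(rel1, tpl1, xout = 0.3 + 0.025)$y
  expect_equal(atHalf, 1, tolerance = 0.02)
  expect_error(
    generateErpTemplate("note_onset", fs,
      list(note_onset = data.frame(latencyMs = 700, amplitude = 1, widthMs = 50))
    ),
    "latency"
  )
})

test_that("background noise has a 1/f^alpha spectrum", {
  set.seed(11)
  x <- ieegerp:::.oneOverFNoise(2^15, 256, 1, 1)
  expect_equal(sd(x), 1, tolerance = 1e-6)
  sp <- spec.pgram(x, spans = 31, taper = 0, plot = FALSE, detrend = FALSE)
  keep <- sp$freq > 0.005 & sp$freq < 0.4 # avoid DC-zeroing and cutoff edges
  fit <- lm(log(sp$spec[keep]) ~ log(sp$freq[keep]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.3)
})

test_that("a noiseless sparse session reproduces the injected template exactly", {
  spec <- syntheticSessionSpec(
    durationS = 20, fs = 512,
    regionNames = c("superior_temporal", "middle_temporal"),
    nChannelsPerRegion = 1, noiseSd = 0, ioiMeanS = 2, ioiJitterS = 0,
    nPhraseBoundaries = 2, iedRateHz = 0, seed = 5
  )
  sess <- generateSession(spec)
  rec <- sess$recording
  tplNote <- generateErpTemplate("note_onset", 512)
  tplPhrase <- generateErpTemplate("phrase_boundary", 512)
  preS <- floor(200 * 512 / 1000)
  isPhrase <- markerTimes(sess$noteOnsets) %in% markerTimes(sess$phraseBoundaries)
  for (i in seq_along(markerTimes(sess$noteOnsets))) {
    tt <- markerTimes(sess$noteOnsets)[i]
    c0 <- round(tt * 512)
    idx <- (c0 - preS + 1):(c0 - preS + length(tplNote))
    want <- if (isPhrase[i]) tplPhrase else tplNote
    # channel 1: region gain +1; channel 2: region gain -1
    expect_equal(rec@data[1, idx], as.numeric(want), tolerance = 1e-12)
    expect_equal(rec@data[2, idx], -as.numeric(want), tolerance = 1e-12)
  }
})

test_that("session generation is bit-reproducible and records IED ground truth", {
  spec <- smallSessionSpec(9, durationS = 20, iedRateHz = 0.05)
  a <- generateSession(spec)
  b <- generateSession(spec)
  expect_identical(a$recording@data, b$recording@data)
  expect_identical(a$groundTruth$iedTimes, b$groundTruth$iedTimes)
  expect_named(a$groundTruth$iedTimes, channelLabels(a$recording))

  # channels without spikes in a null-ERP noiseless session stay flat
  spec0 <- smallSessionSpec(9,
    durationS = 20, noiseSd = 0, iedRateHz = 0.05,
    erpParams = nullErpParams()
  )
  s0 <- generateSession(spec0)
  nSpikes <- lengths(s0$groundTruth$iedTimes)
  for (ch in seq_along(nSpikes)) {
    if (nSpikes[ch] == 0) {
      expect_equal(max(abs(s0$recording@data[ch, ])), 0)
    } else {
      expect_gt(max(abs(s0$recording@data[ch, ])), 0)
      if (nSpikes[ch] == 1) {
        # an isolated spike peaks at iedSnr in units of the (unit) noise SD;
        # overlapping spikes superpose and need not
        expect_equal(max(s0$recording@data[ch, ]), spec0$iedSnr, tolerance = 1e-6)
      }
    }
  }
})

test_that("onset envelopes carry one impulse of the onset's strength per event", {
  track <- MarkerTrack(c(0.5, 1.0, 2.25), "note_onset", c(2, 1, 3))
  env <- generateOnsetEnvelope(track, fsEnv = 100, durationS = 3)
  expect_length(env, 300)
  idx <- round(c(0.5, 1.0, 2.25) * 100) + 1
  expect_equal(env[idx], c(2, 1, 3))
  expect_equal(sum(env), 6) # nothing anywhere else
})
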