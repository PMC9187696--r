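#' Specification of a synthetic iEEG session
#'
#' Describes a simulated listening session with known ground truth: a marker
#' schedule (note onsets with log-normal strengths; phrase boundaries as a
#' quasi-evenly spaced subset coinciding with onsets), 1/f^alpha background
#' noise, Gaussian-component evoked templates injected at every marker, and
#' sporadic interictal spikes at Poisson times. Defaults emulate the study
#' conditions the pipeline targets: a 90 s excerpt sampled at 512 Hz,
#' ~274 note onsets, 8 phrase boundaries, and 34-77 channels spread over
#' eight cortical subregions.
#'
#' @param durationS session length in seconds (default 90).
#' @param fs sampling rate in Hz (default 512).
#' @param regionNames cortical subregions to simulate (default: the eight
#'   subregions the analysis reports).
#' @param nChannelsPerRegion channels per subregion (default 6, i.e. 48
#'   channels over the eight default regions).
#' @param noiseExponent spectral slope alpha of the 1/f^alpha background
#'   (default 1).
#' @param noiseSd background-noise standard deviation in microvolts
#'   (default 10).
#' @param erpParams named list with elements \code{note_onset} and
#'   \code{phrase_boundary}, each a data.frame with columns
#'   \code{latencyMs}, \code{amplitude} (in multiples of \code{noiseSd}) and
#'   \code{widthMs} (FWHM). Defaults: an N1-P2-like pair at 100/200 ms for
#'   note onsets; the phrase template adds components at -150, 400 and
#'   500 ms.
#' @param ioiMeanS,ioiJitterS mean and SD of the note inter-onset interval
#'   in seconds (defaults 0.32 and 0.10; IOIs are truncated below at 60 ms).
#' @param nPhraseBoundaries number of phrase boundaries (default 8).
#' @param iedRateHz Poisson rate of injected interictal spikes per channel
#'   (default 0.01).
#' @param iedSnr interictal-spike peak amplitude in multiples of
#'   \code{noiseSd} (default 5).
#' @param regionGains named numeric vector of per-region multipliers applied
#'   to the injected templates. Default: +1/-1 alternating across regions, a
#'   dipolar-like topography whose spatial mean is (near) zero so that
#'   average re-referencing passes the injected responses through intact; a
#'   spatially uniform topography would be cancelled exactly by the average
#'   reference.
#' @param seed RNG seed; the same spec and seed reproduce the session
#'   bit-identically.
#' @return A validated list of class \code{SyntheticSessionSpec}.
#' @export
syntheticSessionSpec <- function(durationS = 90, fs = 512,
                                 regionNames = REGION_NAMES,
                                 nChannelsPerRegion = 6,
                                 noiseExponent = 1, noiseSd = 10,
                                 erpParams = defaultErpParams(),
                                 ioiMeanS = 0.32, ioiJitterS = 0.10,
                                 nPhraseBoundaries = 8,
                                 iedRateHz = 0.01, iedSnr = 5,
                                 regionGains = NULL, seed = 1L) {
  if (durationS <= 0) stop("durationS must be positive")
  if (fs <= 0) stop("fs must be positive")
  if (nPhraseBoundaries < 0) stop("nPhraseBoundaries must be >= 0")
  if (ioiMeanS <= 0) stop("ioiMeanS must be positive")
  for (kind in names(erpParams)) {
    p <- erpParams[[kind]]
    if (nrow(p) && (any(p$latencyMs < -200) || any(p$latencyMs > 600)))
      stop("ERP component latencies must lie within [-200, 600] ms")
  }
  if (is.null(regionGains)) {
    regionGains <- rep(c(1, -1), length.out = length(regionNames))
    names(regionGains) <- regionNames
  }
  spec <- list(
    durationS = durationS, fs = fs, regionNames = regionNames,
    nChannelsPerRegion = nChannelsPerRegion,
    noiseExponent = noiseExponent, noiseSd = noiseSd,
    erpParams = erpParams, ioiMeanS = ioiMeanS, ioiJitterS = ioiJitterS,
    nPhraseBoundaries = nPhraseBoundaries,
    iedRateHz = iedRateHz, iedSnr = iedSnr,
    regionGains = regionGains, seed = as.integer(seed)
  )
  class(spec) <- c("SyntheticSessionSpec", "list")
  spec
}

#' Default evoked-template parameters
#'
#' The note-onset template is an N1-P2-like biphasic response (negative
#' deflection at 100 ms, positive at 200 ms). The phrase-boundary template
#' carries in addition a prestimulus component at -150 ms and late
#' components at 400 and 500 ms.
#'
#' @return named list of per-kind component tables.
#' @export
defaultErpParams <- function() {
  list(
    note_onset = data.frame(
      latencyMs = c(100, 200), amplitude = c(-1, 1), widthMs = c(60, 80)
    ),
    phrase_boundary = data.frame(
      latencyMs = c(-150, 100, 200, 400, 500),
      amplitude = c(1, -1, 1, 1, 1),
      widthMs = c(80, 60, 80, 100, 100)
    )
  )
}

#' Generate the marker schedule of a synthetic session
#'
#' Note-onset times are a cumulative sum of truncated-normal inter-onset
#' intervals; strengths are log-normal. Phrase boundaries are a quasi-evenly
#' spaced subset of the timeline snapped to the nearest note onset, so every
#' boundary coincides with an onset.
#'
#' @param spec a \code{\link{syntheticSessionSpec}}.
#' @return list with elements \code{noteOnsets} and \code{phraseBoundaries},
#'   both \linkS4class{MarkerTrack}s.
#' @export
generateMarkerSchedule <- function(spec) {
  set.seed(spec$seed)
  .markerScheduleImpl(spec)
}

.markerScheduleImpl <- function(spec) {
  tMax <- spec$durationS - 0.6
  t0 <- 0.5
  nGuess <- ceiling((tMax - t0) / spec$ioiMeanS) + 50L
  iois <- pmax(0.06, rnorm(nGuess, spec$ioiMeanS, spec$ioiJitterS))
  times <- t0 + cumsum(iois)
  times <- c(t0, times[times < tMax])
  strengths <- rlnorm(length(times), meanlog = 0, sdlog = 0.5)
  if (length(times) < spec$nPhraseBoundaries)
    stop(sprintf(
      "cannot place %d phrase boundaries on only %d note onsets",
      spec$nPhraseBoundaries, length(times)
    ))
  notes <- MarkerTrack(times, "note_onset", strengths)
  if (spec$nPhraseBoundaries == 0L) {
    phrases <- MarkerTrack(numeric(0), "phrase_boundary")
  } else {
    targets <- seq(t0 + 1, tMax - 1, length.out = spec$nPhraseBoundaries)
    picked <- integer(0)
    for (tt in targets) {
      ord <- order(abs(times - tt))
      ord <- ord[!(ord %in% picked)]
      picked <- c(picked, ord[1])
    }
    picked <- sort(picked)
    phrases <- MarkerTrack(times[picked], "phrase_boundary", strengths[picked])
  }
  list(noteOnsets = notes, phraseBoundaries = phrases)
}

#' Build an evoked template over the peri-stimulus window
#'
#' The template is a sum of Gaussian-windowed monophasic components
#' (latency, amplitude, FWHM), evaluated on the same grid the segmentation
#' stage uses: \code{floor(preMs*fs/1000) + floor(postMs*fs/1000) + 1}
#' samples with relative time 0 at the stimulus sample.
#'
#' @param kind \code{"note_onset"} or \code{"phrase_boundary"}.
#' @param fs sampling rate, Hz.
#' @param erpParams per-kind component tables (see
#'   \code{\link{defaultErpParams}}).
#' @param preMs,postMs window extent in ms (defaults 200 / 600).
#' @return numeric waveform with attribute \code{relTime} (seconds).
#' @export
generateErpTemplate <- function(kind, fs, erpParams = defaultErpParams(),
                                preMs = 200, postMs = 600) {
  if (fs <= 0) stop("fs must be positive")
  p <- erpParams[[kind]]
  if (is.null(p)) stop(sprintf("no ERP parameters for kind '%s'", kind))
  if (nrow(p) && (any(p$latencyMs < -preMs) || any(p$latencyMs > postMs)))
    stop(sprintf("component latency outside [%g, %g] ms", -preMs, postMs))
  preS <- floor(preMs * fs / 1000)
  postS <- floor(postMs * fs / 1000)
  relTime <- (-preS:postS) / fs
  w <- numeric(length(relTime))
  for (i in seq_len(nrow(p))) {
    sigma <- (p$widthMs[i] / 1000) / (2 * sqrt(2 * log(2)))
    w <- w + p$amplitude[i] * exp(-(relTime - p$latencyMs[i] / 1000)^2 / (2 * sigma^2))
  }
  attr(w, "relTime") <- relTime
  w
}

# 1/f^alpha noise by spectral shaping: white Gaussian spectrum scaled by
# f^(-alpha/2), random phases from the white draw, inverse FFT, rescaled to
# the requested SD. DC is zeroed.
.oneOverFNoise <- function(n, fs, alpha, sdTarget) {
  white <- rnorm(n)
  spec <- fft(white)
  freqs <- c(0, seq_len(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs) # two-sided axis
  shape <- c(0, freqs[-1]^(-alpha / 2))
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0 || sdTarget == 0) return(x * 0)
  x * (sdTarget / s)
}

#' Generate a full synthetic session
#'
#' Produces a \linkS4class{Recording} equal to 1/f^alpha background noise
#' plus region-scaled evoked templates added at every marker time (the
#' phrase template at phrase boundaries, the note template at the remaining
#' note onsets) plus unit-RMS interictal-spike templates at Poisson times,
#' together with the marker tracks and a ground-truth record of everything
#' injected.
#'
#' @param spec a \code{\link{syntheticSessionSpec}}.
#' @return list with elements \code{recording}, \code{noteOnsets},
#'   \code{phraseBoundaries} and \code{groundTruth} (a list holding the
#'   injected marker times, per-channel spike times, region gains and the
#'   template parameters).
#' @export
generateSession <- function(spec) {
  set.seed(spec$seed)
  sched <- .markerScheduleImpl(spec)
  notes <- sched$noteOnsets
  phrases <- sched$phraseBoundaries

  regions <- rep(spec$regionNames, each = spec$nChannelsPerRegion)
  labels <- paste0(regions, "-", sequence(rep(spec$nChannelsPerRegion, length(spec$regionNames))))
  nch <- length(regions)
  n <- round(spec$durationS * spec$fs)

  tplNote <- generateErpTemplate("note_onset", spec$fs, spec$erpParams)
  tplPhrase <- generateErpTemplate("phrase_boundary", spec$fs, spec$erpParams)
  preS <- floor(200 * spec$fs / 1000)
  # amplitudes are in multiples of the noise SD; a noiseless session keeps
  # unit scale so injected shapes remain visible
  ampScale <- if (spec$noiseSd > 0) spec$noiseSd else 1
  iedTpl <- defaultIedTemplate(spec$fs)
  iedWave <- iedTpl@waveform * (spec$iedSnr * ampScale / max(iedTpl@waveform))
  Lied <- length(iedWave)

  isPhrase <- markerTimes(notes) %in% markerTimes(phrases)
  data <- matrix(0, nrow = nch, ncol = n)
  iedTimes <- vector("list", nch)
  names(iedTimes) <- labels
  for (ch in seq_len(nch)) {
    x <- .oneOverFNoise(n, spec$fs, spec$noiseExponent, spec$noiseSd)
    gain <- spec$regionGains[[regions[ch]]]
    anyErp <- gain != 0 && (any(tplNote != 0) || any(tplPhrase != 0)) &&
      any(c(spec$erpParams$note_onset$amplitude,
            spec$erpParams$phrase_boundary$amplitude) != 0)
    if (anyErp) {
      for (i in seq_along(markerTimes(notes))) {
        tt <- markerTimes(notes)[i]
        tpl <- if (isPhrase[i]) tplPhrase else tplNote
        c0 <- round(tt * spec$fs) # 0-based center sample
        idx <- (c0 - preS + 1):(c0 - preS + length(tpl))
        keep <- idx >= 1 & idx <= n
        x[idx[keep]] <- x[idx[keep]] + gain * ampScale * tpl[keep]
      }
    }
    nIed <- rpois(1, spec$iedRateHz * spec$durationS)
    tIed <- sort(runif(nIed, 0.5, spec$durationS - 0.5))
    for (tt in tIed) {
      s0 <- round(tt * spec$fs) - floor(Lied / 2)
      idx <- (s0 + 1):(s0 + Lied)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + iedWave[keep]
    }
    iedTimes[[ch]] <- tIed
    data[ch, ] <- x
  }

  rec <- Recording(data, spec$fs, labels, regions,
    sessionId = sprintf("synthetic-seed%d", spec$seed), subjectId = "synthetic"
  )
  list(
    recording = rec, noteOnsets = notes, phraseBoundaries = phrases,
    groundTruth = list(
      noteTimes = markerTimes(notes), phraseTimes = markerTimes(phrases),
      iedTimes = iedTimes, regionGains = spec$regionGains,
      erpParams = spec$erpParams, iedSnr = spec$iedSnr, noiseSd = spec$noiseSd
    )
  )
}

#' Default interictal-spike template
#'
#' A triphasic spike morphology over 250 ms: a small leading negativity, a
#' sharp positive spike, and a trailing negativity, normalized to unit RMS.
#' Two properties make this shape detectable by normalized correlation:
#' its energy lies above the knee of the 1/f background (a template
#' dominated by a slow wave correlates spuriously with smooth background
#' fluctuations), and its peak-to-RMS ratio is ~2.5, so a spike injected at
#' peak amplitude k times the noise SD carries window RMS ~0.4 k noise SDs
#' and clears high correlation thresholds already at moderate k.
#'
#' @param fs sampling rate, Hz.
#' @return An \linkS4class{IedTemplate}.
#' @export
defaultIedTemplate <- function(fs) {
  t <- seq(0, 0.25, by = 1 / fs)
  w <- -0.4 * exp(-(t - 0.065)^2 / (2 * 0.018^2)) +
    exp(-(t - 0.105)^2 / (2 * 0.013^2)) -
    0.55 * exp(-(t - 0.15)^2 / (2 * 0.026^2))
  IedTemplate(w, fs, name = "triphasic_spike")
}

#' Synthesize an onset-strength envelope from a marker track
#'
#' Places one impulse of height equal to the onset's strength at the sample
#' nearest each onset time, adds Gaussian noise and clips at zero. Used to
#' exercise onset peak picking against known ground truth.
#'
#' @param noteOnsets a \linkS4class{MarkerTrack} of kind note_onset.
#' @param fsEnv envelope sampling rate, Hz.
#' @param noiseSd additive noise SD (default 0).
#' @param seed RNG seed.
#' @param durationS envelope length in seconds (default: last onset + 1 s).
#' @return nonnegative numeric series with attribute \code{fs}.
#' @export
generateOnsetEnvelope <- function(noteOnsets, fsEnv, noiseSd = 0, seed = 1L,
                                  durationS = NULL) {
  if (fsEnv <= 0) stop("fsEnv must be positive")
  times <- markerTimes(noteOnsets)
  if (is.null(durationS))
    durationS <- if (length(times)) max(times) + 1 else 1
  n <- ceiling(durationS * fsEnv)
  env <- numeric(n)
  if (length(times)) {
    idx <- round(times * fsEnv) + 1L
    str <- markerStrengths(noteOnsets)
    str[is.na(str)] <- 1
    env[idx] <- str
  }
  if (noiseSd > 0) {
    set.seed(seed)
    env <- pmax(env + rnorm(n, 0, noiseSd), 0)
  }
  attr(env, "fs") <- fsEnv
  env
}
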