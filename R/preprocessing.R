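#' Preprocessing configuration
#'
#' @param notchHz mains notch frequency in Hz (60; NULL disables).
#' @param bandLoHz,bandHiHz band-pass edges in Hz (1 and 250; NULL disables
#'   the band-pass).
#' @param targetFs decimation target in Hz (256); must divide the recording
#'   rate. Equal to the recording rate means no decimation.
#' @param badChannelK SD multiplier of the bad-channel rule (2.5).
#' @param notchQ notch quality factor (30): the stop band is
#'   notchHz/notchQ wide.
#' @param antiAliasFrac anti-alias low-pass corner as a fraction of
#'   targetFs (0.45).
#' @return validated config list.
#' @export
preprocessConfig <- function(notchHz = 60, bandLoHz = 1, bandHiHz = 250,
                             targetFs = 256, badChannelK = 2.5,
                             notchQ = 30, antiAliasFrac = 0.45) {
  if (!is.null(bandLoHz) && !is.null(bandHiHz) && bandLoHz >= bandHiHz)
    stop("bandLoHz must be below bandHiHz")
  if (badChannelK <= 0) stop("badChannelK must be positive")
  list(
    notchHz = notchHz, bandLoHz = bandLoHz, bandHiHz = bandHiHz,
    targetFs = targetFs, badChannelK = badChannelK,
    notchQ = notchQ, antiAliasFrac = antiAliasFrac
  )
}

#' Exclude bad channels by the RMS-deviation rule
#'
#' Summarizes each channel by the RMS of its raw signal and excludes a
#' channel whenever its summary deviates from the cross-channel median by
#' more than \code{k} standard deviations of the summaries. Exclusion is a
#' single evaluation on the input; re-running on the reduced recording
#' re-evaluates the rule on the survivors.
#'
#' @param rec a \linkS4class{Recording} (raw, before filtering).
#' @param k SD multiplier (default 2.5).
#' @return list with the reduced \code{recording} and the \code{excluded}
#'   channel labels.
#' @export
excludeBadChannels <- function(rec, k = 2.5) {
  if (nChannels(rec) < 3L) stop("need at least 3 channels")
  s <- sqrt(rowMeans(rec@data^2))
  dev <- abs(s - median(s))
  bad <- dev > k * sd(s)
  if (all(bad))
    stop(sprintf(
      "all channels excluded; RMS summaries: %s",
      paste(signif(s, 4), collapse = ", ")
    ))
  out <- new("Recording",
    data = rec@data[!bad, , drop = FALSE], fs = rec@fs,
    channelLabels = rec@channelLabels[!bad],
    channelRegions = rec@channelRegions[!bad],
    sessionId = rec@sessionId, subjectId = rec@subjectId
  )
  list(recording = out, excluded = rec@channelLabels[bad])
}

# Squared magnitude response of an IIR filter (b, a from signal::butter) on
# the length-n FFT grid: |B(e^-iw)/A(e^-iw)|^2 — the transfer function of
# that filter applied forward and backward (zero phase).
.zeroPhaseGain <- function(filt, n) {
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(-1i * w)
  horner <- function(coef) {
    acc <- rep(0 + 0i, n)
    for (c in coef) acc <- acc * z + c
    acc
  }
  Mod(horner(filt$b) / horner(filt$a))^2
}

# Zero-phase filtering of each row by the combined squared-magnitude
# response of a list of IIR sections, via FFT with reflection padding (the
# forward-backward cascade evaluated in the frequency domain; numerically
# stable for corners close to Nyquist).
.zeroPhaseFilterRows <- function(data, filters, fs) {
  n <- ncol(data)
  pad <- min(n - 1L, round(2 * fs))
  np <- n + 2L * pad
  gain <- rep(1, np)
  for (f in filters) gain <- gain * .zeroPhaseGain(f, np)
  out <- data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]))
    yp <- Re(fft(fft(xp) * gain, inverse = TRUE)) / np
    out[ch, ] <- yp[(pad + 1L):(pad + n)]
  }
  out
}

#' Condition a recording: notch, band-pass, average reference, decimate
#'
#' Applies, in order: a zero-phase Butterworth band-stop notch; a
#' zero-phase band-pass (order-4 high-pass and order-4 low-pass Butterworth
#' sections); average re-referencing (the instantaneous cross-channel mean
#' subtracted from every channel); and an anti-alias low-pass followed by
#' integer decimation to \code{targetFs}. Zero-phase filtering — which
#' preserves ERP latencies, the quantity under study — is realized by
#' applying the squared magnitude response of the Butterworth cascade in
#' the frequency domain with reflection padding: the exact transfer
#' function of forward-backward IIR filtering, free of the numerical
#' fragility of time-domain recursion with corners near Nyquist, and one
#' FFT pass per channel. Because all sections are linear and identical
#' across channels they commute with each other and with average
#' referencing, so the anti-alias section is folded into the same pass.
#'
#' @param rec a \linkS4class{Recording}.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return the preprocessed \linkS4class{Recording} at \code{targetFs}.
#' @export
preprocessRecording <- function(rec, cfg = preprocessConfig()) {
  fs <- rec@fs
  if (!is.null(cfg$bandHiHz) && cfg$bandHiHz >= fs / 2)
    stop(sprintf("bandHiHz (%g) must be below Nyquist (%g)", cfg$bandHiHz, fs / 2))
  ratio <- fs / cfg$targetFs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("targetFs (%g) must divide the sampling rate (%g)", cfg$targetFs, fs))
  ratio <- round(ratio)

  filters <- list()
  if (!is.null(cfg$notchHz)) {
    bw <- cfg$notchHz / cfg$notchQ
    filters <- c(filters, list(signal::butter(
      2, c(cfg$notchHz - bw / 2, cfg$notchHz + bw / 2) / (fs / 2), type = "stop"
    )))
  }
  if (!is.null(cfg$bandLoHz))
    filters <- c(filters, list(signal::butter(4, cfg$bandLoHz / (fs / 2), type = "high")))
  if (!is.null(cfg$bandHiHz))
    filters <- c(filters, list(signal::butter(4, cfg$bandHiHz / (fs / 2), type = "low")))
  if (ratio > 1L)
    filters <- c(filters, list(signal::butter(
      6, (cfg$antiAliasFrac * cfg$targetFs) / (fs / 2), type = "low"
    )))

  data <- rec@data
  if (length(filters)) data <- .zeroPhaseFilterRows(data, filters, fs)
  # average reference: subtract the cross-channel mean at every sample
  data <- sweep(data, 2, colMeans(data))
  if (ratio > 1L)
    data <- data[, seq(1, ncol(data), by = ratio), drop = FALSE]
  new("Recording",
    data = data, fs = cfg$targetFs,
    channelLabels = rec@channelLabels, channelRegions = rec@channelRegions,
    sessionId = rec@sessionId, subjectId = rec@subjectId
  )
}
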