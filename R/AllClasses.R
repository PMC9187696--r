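#' @import methods
#' @importFrom stats rnorm runif rpois rlnorm qnorm pchisq shapiro.test sd median fft rbinom
#' @importFrom utils read.table write.table
NULL

REGION_NAMES <- c(
  "superior_temporal", "middle_temporal",
  "rostral_anterior_cingulate", "rostral_middle_frontal",
  "caudal_middle_frontal", "medial_orbitofrontal",
  "superior_frontal", "insular"
)

MARKER_KINDS <- c("note_onset", "phrase_boundary", "reference")

#' Multichannel intracranial recording
#'
#' Container for a channels-by-samples signal matrix in microvolts together
#' with its sampling rate, channel labels, and the cortical subregion each
#' channel is assigned to.
#'
#' @slot data numeric matrix, channels x samples, physical units microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per row of \code{data}.
#' @slot channelRegions character vector, cortical subregion per channel.
#' @slot sessionId,subjectId identifier strings.
#' @export
setClass("Recording",
  slots = c(
    data = "matrix", fs = "numeric",
    channelLabels = "character", channelRegions = "character",
    sessionId = "character", subjectId = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal number of data rows")
  if (nrow(object@data) != length(object@channelRegions))
    msg <- c(msg, "channelRegions length must equal number of data rows")
  if (anyNA(object@data))
    msg <- c(msg, "data must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelLabels,channelRegions per-channel label and subregion.
#' @param sessionId,subjectId identifier strings.
#' @return A \linkS4class{Recording}.
#' @export
Recording <- function(data, fs, channelLabels = NULL, channelRegions = NULL,
                      sessionId = "s1", subjectId = "sub1") {
  data <- as.matrix(data)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(channelRegions)) channelRegions <- rep("other", nrow(data))
  new("Recording",
    data = data, fs = as.numeric(fs),
    channelLabels = as.character(channelLabels),
    channelRegions = as.character(channelRegions),
    sessionId = sessionId, subjectId = subjectId
  )
}

#' Stimulus marker track
#'
#' An ordered set of stimulus event times of one kind (note onsets, phrase
#' boundaries, or between-stimulus reference anchors), optionally carrying a
#' per-event strength (onset-envelope magnitude).
#'
#' @slot times event times in seconds, strictly ascending, all >= 0.
#' @slot kind one of \code{"note_onset"}, \code{"phrase_boundary"},
#'   \code{"reference"}.
#' @slot strengths numeric per-event strength (may be NA).
#' @export
setClass("MarkerTrack",
  slots = c(times = "numeric", kind = "character", strengths = "numeric")
)

setValidity("MarkerTrack", function(object) {
  msg <- character()
  if (!(object@kind %in% MARKER_KINDS))
    msg <- c(msg, sprintf("kind must be one of: %s", paste(MARKER_KINDS, collapse = ", ")))
  if (length(object@times) && any(object@times < 0))
    msg <- c(msg, "all times must be >= 0")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly ascending")
  if (length(object@strengths) != length(object@times))
    msg <- c(msg, "strengths must have one value per time")
  if (length(msg)) msg else TRUE
})

#' Construct a MarkerTrack
#'
#' @param times event times in seconds (strictly ascending).
#' @param kind marker kind.
#' @param strengths optional per-event strengths.
#' @return A \linkS4class{MarkerTrack}.
#' @export
MarkerTrack <- function(times, kind, strengths = NULL) {
  times <- as.numeric(times)
  if (is.null(strengths)) strengths <- rep(NA_real_, length(times))
  new("MarkerTrack", times = times, kind = kind, strengths = as.numeric(strengths))
}

#' Per-channel stack of peri-stimulus windows
#'
#' All equal-length windows cut around the markers of one condition, kept
#' separately per channel (windows x samples x channels) so that artifact
#' rejection can act before region averaging.
#'
#' @slot windows 3-d array: n_windows x n_samples x n_channels.
#' @slot relTime relative time axis in seconds, from -pre to +post; the
#'   sample at the stimulus has relative time 0.
#' @slot condition marker kind the windows were cut around.
#' @slot sourceTimes absolute marker time (s) per window.
#' @slot fs sampling rate of the windows, Hz.
#' @slot channelLabels,channelRegions per-channel metadata.
#' @export
setClass("ErpWindowArray",
  slots = c(
    windows = "array", relTime = "numeric", condition = "character",
    sourceTimes = "numeric", fs = "numeric",
    channelLabels = "character", channelRegions = "character"
  )
)

setValidity("ErpWindowArray", function(object) {
  msg <- character()
  d <- dim(object@windows)
  if (length(d) != 3L) msg <- c(msg, "windows must be a 3-d array")
  else {
    if (d[2] != length(object@relTime))
      msg <- c(msg, "relTime must have one value per sample")
    if (d[1] != length(object@sourceTimes))
      msg <- c(msg, "sourceTimes must have one value per window")
    if (d[3] != length(object@channelLabels) || d[3] != length(object@channelRegions))
      msg <- c(msg, "channel metadata must match the channel dimension")
  }
  if (!(object@condition %in% MARKER_KINDS))
    msg <- c(msg, "condition must be a marker kind")
  if (length(msg)) msg else TRUE
})

#' Region-averaged window set for one condition
#'
#' A stack of equal-length peri-stimulus windows for one condition and one
#' cortical subregion, sharing a relative time axis.
#'
#' @slot windows n_windows x n_samples matrix (microvolts).
#' @slot relTime relative time axis in seconds; 0 at the stimulus sample.
#' @slot condition marker kind.
#' @slot region subregion name.
#' @slot sourceTimes absolute marker time (s) per window.
#' @slot fs sampling rate, Hz.
#' @export
setClass("ErpWindowSet",
  slots = c(
    windows = "matrix", relTime = "numeric", condition = "character",
    region = "character", sourceTimes = "numeric", fs = "numeric"
  )
)

setValidity("ErpWindowSet", function(object) {
  msg <- character()
  if (ncol(object@windows) != length(object@relTime))
    msg <- c(msg, "relTime must have one value per sample")
  if (nrow(object@windows) != length(object@sourceTimes))
    msg <- c(msg, "sourceTimes must have one value per window")
  if (!(object@condition %in% MARKER_KINDS))
    msg <- c(msg, "condition must be a marker kind")
  if (length(object@relTime) && min(abs(object@relTime)) > 1e-9)
    msg <- c(msg, "relTime must contain the stimulus sample (t = 0)")
  if (length(msg)) msg else TRUE
})

#' Unit-normalized interictal spike template
#'
#' @slot waveform template samples at \code{fs}, normalized to unit RMS.
#' @slot fs sampling rate, Hz.
#' @slot name template identifier.
#' @export
setClass("IedTemplate",
  slots = c(waveform = "numeric", fs = "numeric", name = "character")
)

setValidity("IedTemplate", function(object) {
  msg <- character()
  if (!all(is.finite(object@waveform))) msg <- c(msg, "waveform must be finite")
  rms <- sqrt(mean(object@waveform^2))
  if (abs(rms - 1) > 1e-6) msg <- c(msg, "waveform must have unit RMS")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an IedTemplate (normalizing to unit RMS)
#'
#' @param waveform numeric template samples.
#' @param fs sampling rate, Hz.
#' @param name template identifier.
#' @return An \linkS4class{IedTemplate}.
#' @export
IedTemplate <- function(waveform, fs, name = "ied") {
  waveform <- as.numeric(waveform)
  rms <- sqrt(mean(waveform^2))
  if (!is.finite(rms) || rms == 0) stop("template waveform must have nonzero RMS")
  new("IedTemplate", waveform = waveform / rms, fs = as.numeric(fs), name = name)
}

#' Result of a cluster-level permutation test
#'
#' @slot zSeries per-timepoint Mann-Whitney Z score (condition A vs B).
#' @slot relTime relative time axis in seconds.
#' @slot clusters data.frame with one row per temporal cluster: start/end
#'   sample index (1-based, inclusive), start/end in ms, sign, stat
#'   (max |Z| in the cluster), p (permutation p-value) and significant flag.
#' @slot threshold cluster-forming |Z| threshold used.
#' @slot nA,nB window counts of the two conditions.
#' @slot conditionA,conditionB,region provenance labels.
#' @export
setClass("ClusterTestResult",
  slots = c(
    zSeries = "numeric", relTime = "numeric", clusters = "data.frame",
    threshold = "numeric", nA = "integer", nB = "integer",
    conditionA = "character", conditionB = "character", region = "character"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  if (length(object@zSeries) != length(object@relTime))
    msg <- c(msg, "zSeries and relTime must have equal length")
  cl <- object@clusters
  if (nrow(cl)) {
    if (any(cl$start < 1L) || any(cl$end > length(object@zSeries)))
      msg <- c(msg, "clusters must lie within the window")
    if (any(cl$p <= 0) || any(cl$p > 1))
      msg <- c(msg, "cluster p-values must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-session integration result
#'
#' @slot relTime shared relative time axis in seconds.
#' @slot counts region x timepoint matrix: number of sessions with a
#'   significant cluster covering each timepoint.
#' @slot shading named list (per region) of data.frames with columns
#'   startMs, endMs, level ("light" / "dark").
#' @slot summary data.frame with one row per subregion: nClusters, meanP,
#'   sdP over the significant clusters pooled across sessions.
#' @slot nSessions number of sessions integrated.
#' @export
setClass("IntegrationResult",
  slots = c(
    relTime = "numeric", counts = "matrix", shading = "list",
    summary = "data.frame", nSessions = "integer"
  )
)

setValidity("IntegrationResult", function(object) {
  msg <- character()
  if (ncol(object@counts) != length(object@relTime))
    msg <- c(msg, "counts must have one column per timepoint")
  if (length(object@counts) &&
      (min(object@counts) < 0 || max(object@counts) > object@nSessions))
    msg <- c(msg, "counts must lie in [0, nSessions]")
  if (length(msg)) msg else TRUE
})
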