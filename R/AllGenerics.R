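#' Number of channels
#' @param x a \linkS4class{Recording} or \linkS4class{ErpWindowArray}.
#' @return integer count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of windows
#' @param x an \linkS4class{ErpWindowSet} or \linkS4class{ErpWindowArray}.
#' @return integer count.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' Sampling rate in Hz
#' @param x an object carrying a sampling rate.
#' @return numeric scalar, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel subregion assignments
#' @param x a \linkS4class{Recording} or \linkS4class{ErpWindowArray}.
#' @return character vector, one subregion per channel.
#' @export
setGeneric("channelRegions", function(x) standardGeneric("channelRegions"))

#' Channel labels
#' @param x a \linkS4class{Recording} or \linkS4class{ErpWindowArray}.
#' @return character vector.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Event times in seconds
#' @param x a \linkS4class{MarkerTrack}.
#' @return numeric vector, seconds.
#' @export
setGeneric("markerTimes", function(x) standardGeneric("markerTimes"))

#' Per-event strengths
#' @param x a \linkS4class{MarkerTrack}.
#' @return numeric vector.
#' @export
setGeneric("markerStrengths", function(x) standardGeneric("markerStrengths"))

#' Temporal clusters of a test result
#' @param x a \linkS4class{ClusterTestResult}.
#' @param significantOnly keep only clusters with p <= alpha flag.
#' @return data.frame of clusters.
#' @export
setGeneric("clusters", function(x, significantOnly = FALSE) standardGeneric("clusters"))

setMethod("nChannels", "Recording", function(x) nrow(x@data))
setMethod("nChannels", "ErpWindowArray", function(x) dim(x@windows)[3])
setMethod("nWindows", "ErpWindowSet", function(x) nrow(x@windows))
setMethod("nWindows", "ErpWindowArray", function(x) dim(x@windows)[1])
setMethod("samplingRate", "Recording", function(x) x@fs)
setMethod("samplingRate", "ErpWindowSet", function(x) x@fs)
setMethod("samplingRate", "ErpWindowArray", function(x) x@fs)
setMethod("samplingRate", "IedTemplate", function(x) x@fs)
setMethod("channelRegions", "Recording", function(x) x@channelRegions)
setMethod("channelRegions", "ErpWindowArray", function(x) x@channelRegions)
setMethod("channelLabels", "Recording", function(x) x@channelLabels)
setMethod("channelLabels", "ErpWindowArray", function(x) x@channelLabels)
setMethod("markerTimes", "MarkerTrack", function(x) x@times)
setMethod("markerStrengths", "MarkerTrack", function(x) x@strengths)

setMethod("clusters", "ClusterTestResult", function(x, significantOnly = FALSE) {
  cl <- x@clusters
  if (significantOnly && nrow(cl)) cl <- cl[cl$significant, , drop = FALSE]
  cl
})

setMethod("length", "MarkerTrack", function(x) length(x@times))

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording '%s' (subject '%s'): %d channels x %d samples @ %g Hz (%.1f s)\n",
    object@sessionId, object@subjectId, nrow(object@data), ncol(object@data),
    object@fs, ncol(object@data) / object@fs
  ))
  tab <- table(object@channelRegions)
  cat("  regions:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "MarkerTrack", function(object) {
  cat(sprintf("MarkerTrack: %d %s events", length(object@times), object@kind))
  if (length(object@times))
    cat(sprintf(" in [%.3f, %.3f] s", min(object@times), max(object@times)))
  cat("\n")
})

setMethod("show", "ErpWindowArray", function(object) {
  d <- dim(object@windows)
  cat(sprintf(
    "ErpWindowArray (%s): %d windows x %d samples x %d channels @ %g Hz\n",
    object@condition, d[1], d[2], d[3], object@fs
  ))
})

setMethod("show", "ErpWindowSet", function(object) {
  cat(sprintf(
    "ErpWindowSet (%s, region %s): %d windows x %d samples @ %g Hz, t in [%g, %g] ms\n",
    object@condition, object@region, nrow(object@windows), ncol(object@windows),
    object@fs, 1000 * min(object@relTime), 1000 * max(object@relTime)
  ))
})

setMethod("show", "ClusterTestResult", function(object) {
  nsig <- if (nrow(object@clusters)) sum(object@clusters$significant) else 0L
  cat(sprintf(
    "ClusterTestResult [%s vs %s, region %s]: %d clusters (%d significant), |Z| threshold %.3f, n = %d vs %d\n",
    object@conditionA, object@conditionB, object@region,
    nrow(object@clusters), nsig, object@threshold, object@nA, object@nB
  ))
  if (nrow(object@clusters)) {
    cl <- object@clusters
    for (i in seq_len(nrow(cl))) {
      cat(sprintf(
        "  [%+.0f, %+.0f] ms  sign %+d  max|Z| %.2f  p = %.4f%s\n",
        cl$startMs[i], cl$endMs[i], cl$sign[i], cl$stat[i], cl$p[i],
        if (cl$significant[i]) " *" else ""
      ))
    }
  }
})

setMethod("show", "IntegrationResult", function(object) {
  cat(sprintf(
    "IntegrationResult: %d sessions, %d regions x %d timepoints\n",
    object@nSessions, nrow(object@counts), ncol(object@counts)
  ))
  if (nrow(object@summary)) {
    cat("  significant-cluster summary:\n")
    print(object@summary, row.names = FALSE)
  }
})
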