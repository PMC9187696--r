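#' Write / read a Recording as a matrix file with a JSON header
#'
#' The signal matrix (channels x samples, microvolts) is stored as a
#' headerless tab-separated file \code{<prefix>.tsv}, one row per channel;
#' the sampling rate, channel labels, subregions and identifiers go to
#' \code{<prefix>.json}.
#'
#' @param rec a \linkS4class{Recording}.
#' @param prefix path prefix (without extension).
#' @return \code{writeRecording}: the prefix, invisibly;
#'   \code{readRecording}: a \linkS4class{Recording}.
#' @export
writeRecording <- function(rec, prefix) {
  write.table(rec@data, paste0(prefix, ".tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE
  )
  jsonlite::write_json(
    list(
      fs = rec@fs, channelLabels = rec@channelLabels,
      channelRegions = rec@channelRegions,
      sessionId = rec@sessionId, subjectId = rec@subjectId
    ),
    paste0(prefix, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname writeRecording
#' @export
readRecording <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  data <- as.matrix(read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(data) <- NULL
  Recording(data, hdr$fs, hdr$channelLabels, hdr$channelRegions,
    sessionId = hdr$sessionId, subjectId = hdr$subjectId
  )
}

#' Write / read a MarkerTrack as an events TSV
#'
#' Columns: onset_s, kind, strength (NA allowed).
#'
#' @param track a \linkS4class{MarkerTrack}.
#' @param path TSV file path.
#' @return \code{readMarkerTrack}: a \linkS4class{MarkerTrack}.
#' @export
writeMarkerTrack <- function(track, path) {
  df <- data.frame(
    onset_s = track@times,
    kind = rep(track@kind, length(track@times)),
    strength = track@strengths
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMarkerTrack
#' @export
readMarkerTrack <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "kind") %in% names(df)))
    stop("events TSV must have columns onset_s and kind")
  kind <- unique(df$kind)
  if (length(kind) > 1L) stop("events TSV mixes marker kinds")
  MarkerTrack(df$onset_s, kind,
    if ("strength" %in% names(df)) df$strength else NULL
  )
}

#' Read a channel -> subregion map
#'
#' @param path TSV with columns label, region.
#' @return data.frame with columns label and region.
#' @export
readChannelMap <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("label", "region") %in% names(df)))
    stop("channel map must have columns label and region")
  df
}

#' Read / write the pipeline configuration as JSON
#'
#' Unknown keys at the section or option level are rejected so that a typo
#' cannot silently fall back to a default.
#'
#' @param path JSON file path.
#' @return \code{readPipelineConfig}: a \code{\link{pipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipelineConfig()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s", paste(unknown, collapse = ", ")))
  for (sec in names(raw)) {
    if (is.list(base[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(base[[sec]]))
      if (length(bad))
        stop(sprintf(
          "unknown key(s) in section '%s': %s", sec, paste(bad, collapse = ", ")
        ))
      base[[sec]][names(raw[[sec]])] <- raw[[sec]]
    } else {
      base[[sec]] <- raw[[sec]]
    }
  }
  base
}

#' @rdname readPipelineConfig
#' @param config a \code{\link{pipelineConfig}}.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Flatten session cluster results to one row per cluster
#'
#' @param sessionResult the bundle returned by \code{\link{runSession}}.
#' @param sessionId overrides the session identifier column.
#' @return data.frame with columns session, comparison, region, t_start_ms,
#'   t_end_ms, sign, max_abs_z, p, significant.
#' @export
clusterTable <- function(sessionResult, sessionId = NULL) {
  if (is.null(sessionId)) sessionId <- sessionResult$sessionId
  rows <- list()
  for (cmp in names(sessionResult$results)) {
    for (rg in names(sessionResult$results[[cmp]])) {
      cl <- clusters(sessionResult$results[[cmp]][[rg]])
      if (!nrow(cl)) next
      rows[[length(rows) + 1L]] <- data.frame(
        session = sessionId, comparison = cmp, region = rg,
        t_start_ms = cl$startMs, t_end_ms = cl$endMs, sign = cl$sign,
        max_abs_z = cl$stat, p = cl$p, significant = cl$significant
      )
    }
  }
  if (!length(rows))
    return(data.frame(
      session = character(0), comparison = character(0), region = character(0),
      t_start_ms = numeric(0), t_end_ms = numeric(0), sign = numeric(0),
      max_abs_z = numeric(0), p = numeric(0), significant = logical(0)
    ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the flat cluster table as TSV
#'
#' @param tab data.frame from \code{\link{clusterTable}}.
#' @param path output TSV path.
#' @export
writeClusterTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
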