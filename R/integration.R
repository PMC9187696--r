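#' Per-timepoint significant-session counts for one subregion
#'
#' The count at a timepoint is the number of sessions having at least one
#' significant cluster whose extent contains that timepoint.
#'
#' @param results list of \linkS4class{ClusterTestResult}, one per session,
#'   all for the same subregion and comparison.
#' @return integer vector, one count per timepoint.
#' @export
significanceCounts <- function(results) {
  if (!length(results)) stop("need at least one session result")
  relTime <- results[[1]]@relTime
  for (r in results) {
    if (length(r@relTime) != length(relTime) ||
        max(abs(r@relTime - relTime)) > 1e-9)
      stop("session results do not share a relative time axis")
  }
  counts <- integer(length(relTime))
  for (r in results) {
    cl <- clusters(r, significantOnly = TRUE)
    covered <- rep(FALSE, length(relTime))
    for (i in seq_len(nrow(cl))) covered[cl$start[i]:cl$end[i]] <- TRUE
    counts <- counts + covered
  }
  counts
}

#' Shading intervals from significant-session counts
#'
#' Maximal runs of timepoints where the count reaches \code{nLight} sessions
#' are emitted at level "light", runs reaching \code{nDark} at level "dark";
#' every dark interval is nested in a light interval whenever
#' \code{nLight <= nDark}.
#'
#' @param counts integer counts per timepoint.
#' @param relTime relative time axis, seconds.
#' @param nLight,nDark session-count thresholds (defaults 6 and 10).
#' @return data.frame with columns startMs, endMs, level.
#' @export
shadingIntervals <- function(counts, relTime, nLight = 6, nDark = 10) {
  runsAtLeast <- function(thr, level) {
    ok <- counts >= thr
    if (!any(ok)) return(NULL)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(
      startMs = 1000 * relTime[starts[keep]],
      endMs = 1000 * relTime[ends[keep]],
      level = level, stringsAsFactors = FALSE
    )
  }
  out <- rbind(runsAtLeast(nLight, "light"), runsAtLeast(nDark, "dark"))
  if (is.null(out))
    out <- data.frame(startMs = numeric(0), endMs = numeric(0), level = character(0))
  out
}

#' Pooled cluster summary rows per subregion
#'
#' Pools the significant clusters of all sessions within each subregion and
#' reports their count and the mean and SD (population convention, ddof 0)
#' of their p-values, rounded to 3 decimals. Subregions with no significant
#' cluster get count 0 and NA statistics.
#'
#' @param resultsByRegion named list: subregion -> list of
#'   \linkS4class{ClusterTestResult} (one per session).
#' @return data.frame with columns region, nClusters, meanP, sdP.
#' @export
clusterSummaryTable <- function(resultsByRegion) {
  rows <- lapply(names(resultsByRegion), function(rg) {
    ps <- unlist(lapply(resultsByRegion[[rg]], function(r) {
      clusters(r, significantOnly = TRUE)$p
    }))
    if (!length(ps)) {
      data.frame(region = rg, nClusters = 0L, meanP = NA_real_, sdP = NA_real_)
    } else {
      data.frame(
        region = rg, nClusters = length(ps),
        meanP = round(mean(ps), 3),
        sdP = round(sqrt(mean((ps - mean(ps))^2)), 3)
      )
    }
  })
  do.call(rbind, rows)
}

#' Integrate per-session cluster results across sessions
#'
#' @param resultsByRegion named list: subregion -> list of
#'   \linkS4class{ClusterTestResult}, one per session.
#' @param nLight,nDark shading thresholds in sessions (6 and 10).
#' @return an \linkS4class{IntegrationResult}.
#' @export
integrateSessions <- function(resultsByRegion, nLight = 6, nDark = 10) {
  if (!length(resultsByRegion)) stop("no regions to integrate")
  relTime <- resultsByRegion[[1]][[1]]@relTime
  nSessions <- length(resultsByRegion[[1]])
  counts <- matrix(0L, nrow = length(resultsByRegion), ncol = length(relTime),
    dimnames = list(names(resultsByRegion), NULL)
  )
  shading <- list()
  for (rg in names(resultsByRegion)) {
    counts[rg, ] <- significanceCounts(resultsByRegion[[rg]])
    shading[[rg]] <- shadingIntervals(counts[rg, ], relTime, nLight, nDark)
  }
  new("IntegrationResult",
    relTime = relTime, counts = counts, shading = shading,
    summary = clusterSummaryTable(resultsByRegion),
    nSessions = as.integer(nSessions)
  )
}
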