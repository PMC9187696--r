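#' Pick note onsets from an onset-strength envelope
#'
#' Candidate onsets are strict local maxima of the envelope separated by at
#' least a minimum inter-onset gap (greedy suppression: stronger peaks
#' silence weaker peaks within the gap). Of the candidates, the
#' \code{ceiling(keepFraction * n)} with the largest envelope values are
#' retained — the weak-onset exclusion step — with ties broken in favour of
#' earlier peaks.
#'
#' @param envelope nonnegative numeric series.
#' @param fsEnv envelope sampling rate, Hz.
#' @param keepFraction fraction of candidates to keep (default 0.5).
#' @param minGapS minimum inter-peak gap in seconds (default 0.05).
#' @return a \linkS4class{MarkerTrack} of kind note_onset whose strengths
#'   are the envelope values at the retained peaks.
#' @export
pickNoteOnsets <- function(envelope, fsEnv, keepFraction = 0.5, minGapS = 0.05) {
  if (!length(envelope)) stop("envelope is empty")
  if (keepFraction <= 0 || keepFraction > 1) stop("keepFraction must be in (0, 1]")
  env <- as.numeric(envelope)
  n <- length(env)
  if (n < 3L) stop("envelope too short for peak picking")
  isPeak <- which(env[2:(n - 1)] > env[1:(n - 2)] & env[2:(n - 1)] > env[3:n]) + 1L
  if (!length(isPeak)) stop("envelope has no strict local maxima")
  # greedy minimum-gap suppression, strongest first (earlier wins ties)
  gap <- minGapS * fsEnv
  ord <- isPeak[order(-env[isPeak], isPeak)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= gap)) kept <- c(kept, i)
  }
  cand <- sort(kept)
  nKeep <- ceiling(keepFraction * length(cand))
  sel <- cand[order(-env[cand], cand)][seq_len(nKeep)]
  sel <- sort(sel)
  MarkerTrack((sel - 1) / fsEnv, "note_onset", env[sel])
}

#' Dynamic time warping of two feature sequences
#'
#' Classic dynamic program over steps (1,0), (0,1), (1,1): finds the
#' monotone path through the local-cost matrix from (1,1) to (n,m) with
#' minimal cumulative cost.
#'
#' @param featA,featB numeric vectors, or matrices with one feature vector
#'   per row (equal number of columns).
#' @param localCost function of two feature vectors returning a nonnegative
#'   cost (default: Euclidean distance).
#' @return list with \code{path} (two-column integer matrix of 1-based index
#'   pairs, first row c(1,1), last row c(n,m)) and \code{totalCost}.
#' @export
dtwAlign <- function(featA, featB, localCost = NULL) {
  if (is.null(dim(featA))) featA <- matrix(featA, ncol = 1)
  if (is.null(dim(featB))) featB <- matrix(featB, ncol = 1)
  if (ncol(featA) != ncol(featB))
    stop(sprintf(
      "feature dimensionality mismatch: %d vs %d", ncol(featA), ncol(featB)
    ))
  n <- nrow(featA); m <- nrow(featB)
  if (n == 0L || m == 0L) stop("sequences must be non-empty")
  if (is.null(localCost)) localCost <- function(a, b) sqrt(sum((a - b)^2))
  C <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    C[i, j] <- localCost(featA[i, ], featB[j, ])
  D <- matrix(Inf, n, m)
  D[1, 1] <- C[1, 1]
  for (j in seq_len(m)[-1]) D[1, j] <- D[1, j - 1] + C[1, j]
  for (i in seq_len(n)[-1]) {
    D[i, 1] <- D[i - 1, 1] + C[i, 1]
    for (j in seq_len(m)[-1])
      D[i, j] <- C[i, j] + min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
  }
  # backtrack, preferring the diagonal on ties
  path <- matrix(c(n, m), ncol = 2)
  i <- n; j <- m
  while (i > 1L || j > 1L) {
    if (i == 1L) j <- j - 1L
    else if (j == 1L) i <- i - 1L
    else {
      opts <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      k <- which.min(opts)
      if (k == 1L) { i <- i - 1L; j <- j - 1L }
      else if (k == 2L) i <- i - 1L
      else j <- j - 1L
    }
    path <- rbind(c(i, j), path)
  }
  colnames(path) <- c("a", "b")
  list(path = path, totalCost = D[n, m])
}

#' Transfer score-annotated boundary times onto audio time
#'
#' Each score-side boundary time is mapped to the audio time of the warp-path
#' pair whose score frame lies nearest to it; the mapped times are sorted and
#' deduplicated.
#'
#' @param scoreTimesS boundary times (s) on the score timeline.
#' @param scoreFrameTimes frame times (s) of the score feature sequence.
#' @param audioFrameTimes frame times (s) of the audio feature sequence.
#' @param path warp path from \code{\link{dtwAlign}} (two-column matrix).
#' @return a \linkS4class{MarkerTrack} of kind phrase_boundary.
#' @export
mapPhraseBoundaries <- function(scoreTimesS, scoreFrameTimes, audioFrameTimes, path) {
  if (any(scoreTimesS < min(scoreFrameTimes) - 1e-9) ||
      any(scoreTimesS > max(scoreFrameTimes) + 1e-9))
    stop("score time outside the score frame grid")
  pathScoreT <- scoreFrameTimes[path[, 1]]
  pathAudioT <- audioFrameTimes[path[, 2]]
  mapped <- vapply(scoreTimesS, function(s) {
    pathAudioT[which.min(abs(pathScoreT - s))]
  }, numeric(1))
  mapped <- sort(unique(mapped))
  MarkerTrack(mapped, "phrase_boundary")
}
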