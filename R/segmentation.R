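#' Segmentation configuration
#'
#' @param preMs window extent before the stimulus, ms (200).
#' @param postMs window extent after the stimulus, ms (600).
#' @param nReference target number of between-stimulus reference windows
#'   (44).
#' @param resampleN bootstrap size used for the statistical stage (200).
#' @param maxOverlapFrac initial allowed overlap fraction between a
#'   reference window and any other window (0); relaxed in steps of 0.1 if
#'   the target count cannot be met.
#' @param maxRelaxFrac ceiling of the relaxation ladder (1). Set to 0 to
#'   forbid any overlap, in which case dense stimulus schedules make
#'   reference sampling fail.
#' @param seed RNG seed for reference sampling and bootstrap resampling.
#' @return validated config list.
#' @export
segmentationConfig <- function(preMs = 200, postMs = 600, nReference = 44,
                               resampleN = 200, maxOverlapFrac = 0,
                               maxRelaxFrac = 1, seed = 1L) {
  if (preMs < 0 || postMs < 0) stop("preMs and postMs must be >= 0")
  if (resampleN <= 0) stop("resampleN must be positive")
  list(
    preMs = preMs, postMs = postMs, nReference = nReference,
    resampleN = resampleN, maxOverlapFrac = maxOverlapFrac,
    maxRelaxFrac = maxRelaxFrac, seed = as.integer(seed)
  )
}

.windowGeometry <- function(fs, preMs, postMs) {
  preS <- floor(preMs * fs / 1000)
  postS <- floor(postMs * fs / 1000)
  list(preS = preS, postS = postS, len = preS + postS + 1L,
       relTime = (-preS:postS) / fs)
}

#' Cut peri-stimulus windows around marker times
#'
#' For a marker at time t, the center sample is \code{round(t*fs)} (0-based)
#' and the window spans \code{floor(preMs*fs/1000)} samples before to
#' \code{floor(postMs*fs/1000)} samples after it, inclusive — 205 samples at
#' 256 Hz with the default 200/600 ms extents. Markers whose window would
#' leave the recording are dropped and counted.
#'
#' @param rec a preprocessed \linkS4class{Recording}.
#' @param markers a \linkS4class{MarkerTrack}.
#' @param cfg a \code{\link{segmentationConfig}}.
#' @return an \linkS4class{ErpWindowArray} (windows x samples x channels)
#'   with attribute \code{nDropped}.
#' @export
segmentWindows <- function(rec, markers, cfg = segmentationConfig()) {
  g <- .windowGeometry(rec@fs, cfg$preMs, cfg$postMs)
  n <- ncol(rec@data)
  c0 <- round(markerTimes(markers) * rec@fs) # 0-based center sample
  ok <- (c0 - g$preS) >= 0 & (c0 + g$postS) <= (n - 1)
  nDropped <- sum(!ok)
  if (!any(ok))
    stop("no marker yields a full window within the recording")
  c0 <- c0[ok]
  times <- markerTimes(markers)[ok]
  nch <- nChannels(rec)
  win <- array(0, dim = c(length(c0), g$len, nch))
  for (w in seq_along(c0)) {
    idx <- (c0[w] - g$preS + 1L):(c0[w] + g$postS + 1L)
    win[w, , ] <- t(rec@data[, idx, drop = FALSE])
  }
  out <- new("ErpWindowArray",
    windows = win, relTime = g$relTime, condition = markers@kind,
    sourceTimes = times, fs = rec@fs,
    channelLabels = rec@channelLabels, channelRegions = rec@channelRegions
  )
  attr(out, "nDropped") <- nDropped
  out
}

#' Sample reference windows between note onsets
#'
#' Draws candidate window centers uniformly over the recording (seeded) and
#' accepts a candidate only if its window overlaps neither a note-onset
#' peri-stimulus window nor a previously accepted reference window by more
#' than the currently allowed fraction of the window length (initially
#' \code{maxOverlapFrac}, default 0, i.e. disjoint). Because the stimulus
#' and reference windows share one shape, both constraints reduce to a
#' minimum distance between window centers of
#' \code{(1 - frac) * windowLength}. If the target count cannot be reached,
#' the allowed fraction is relaxed in steps of 0.1 up to
#' \code{maxRelaxFrac} — "as little overlapping as possible" — with every
#' relaxation reported via \code{message}; under a dense stimulus schedule
#' (inter-onset intervals shorter than the window) this is the only way any
#' reference window exists at all. Fewer than 2 windows at the relaxation
#' ceiling is an error.
#'
#' @param rec a preprocessed \linkS4class{Recording}.
#' @param noteOnsets the note-onset \linkS4class{MarkerTrack}.
#' @param cfg a \code{\link{segmentationConfig}}.
#' @return an \linkS4class{ErpWindowArray} with condition
#'   \code{"reference"}.
#' @export
sampleReferenceWindows <- function(rec, noteOnsets, cfg = segmentationConfig()) {
  g <- .windowGeometry(rec@fs, cfg$preMs, cfg$postMs)
  dur <- ncol(rec@data) / rec@fs
  winLen <- (g$len - 1L) / rec@fs
  if (dur <= winLen) stop("recording shorter than one window")
  pre <- g$preS / rec@fs
  post <- g$postS / rec@fs
  onsetT <- markerTimes(noteOnsets)

  cLo <- pre
  cHi <- dur - post - 1 / rec@fs
  # smallest onset-overlap any candidate can achieve: jump the ladder there
  if (length(onsetT)) {
    gapPts <- sort(c(cLo, cHi, pmin(pmax((onsetT[-1] + onsetT[-length(onsetT)]) / 2, cLo), cHi)))
    dBest <- max(vapply(gapPts, function(c) min(abs(c - onsetT)), numeric(1)))
    minFrac <- max(0, 1 - dBest / winLen)
  } else minFrac <- 0

  set.seed(cfg$seed)
  accepted <- numeric(0)
  frac <- cfg$maxOverlapFrac
  while (frac < minFrac - 1e-12 && frac < cfg$maxRelaxFrac) {
    frac <- min(frac + 0.1, cfg$maxRelaxFrac)
    message(sprintf(
      "reference sampling: no candidate satisfies overlap fraction; relaxing to %.1f", frac
    ))
  }
  repeat {
    dReq <- (1 - frac) * winLen - 1e-12
    attempts <- 0L
    maxAttempts <- 200L * cfg$nReference
    while (length(accepted) < cfg$nReference && attempts < maxAttempts) {
      attempts <- attempts + 1L
      tc <- runif(1, cLo, cHi)
      if (length(onsetT) && min(abs(tc - onsetT)) < dReq) next
      if (length(accepted) && min(abs(tc - accepted)) < dReq) next
      accepted <- c(accepted, tc)
    }
    if (length(accepted) >= cfg$nReference || frac >= cfg$maxRelaxFrac) break
    frac <- min(frac + 0.1, cfg$maxRelaxFrac)
    message(sprintf(
      "reference sampling: relaxing allowed overlap fraction to %.1f (%d/%d accepted)",
      frac, length(accepted), cfg$nReference
    ))
  }
  if (length(accepted) < 2L)
    stop(sprintf(
      "only %d reference window(s) obtainable between note onsets",
      length(accepted)
    ))
  track <- MarkerTrack(sort(accepted), "reference")
  out <- segmentWindows(rec, track, cfg)
  attr(out, "overlapFracUsed") <- frac
  out
}

#' Average window stacks across channels within each subregion
#'
#' For each subregion present, every window is replaced by the mean over
#' that region's channels; window count and time axis are unchanged.
#'
#' @param arr an \linkS4class{ErpWindowArray}.
#' @param regions subregions to emit (default: all present); a requested
#'   region with no channels is omitted with a \code{message}.
#' @return named list of \linkS4class{ErpWindowSet}, one per subregion.
#' @export
averageByRegion <- function(arr, regions = NULL) {
  if (is.null(regions)) regions <- unique(arr@channelRegions)
  out <- list()
  for (r in regions) {
    sel <- which(arr@channelRegions == r)
    if (!length(sel)) {
      message(sprintf("region '%s' has no channels; omitted", r))
      next
    }
    m <- apply(arr@windows[, , sel, drop = FALSE], c(1, 2), mean)
    m <- matrix(m, nrow = dim(arr@windows)[1])
    out[[r]] <- new("ErpWindowSet",
      windows = m, relTime = arr@relTime, condition = arr@condition,
      region = r, sourceTimes = arr@sourceTimes, fs = arr@fs
    )
  }
  out
}

#' Bootstrap-resample a window set to a fixed count
#'
#' Draws \code{n} windows uniformly with replacement (seeded), for both up-
#' and down-sampling, so the statistical stage always sees the same group
#' size. The drawn source indices are attached as attribute
#' \code{sourceIndices}.
#'
#' @param ws an \linkS4class{ErpWindowSet}.
#' @param n output window count (default 200).
#' @param seed RNG seed.
#' @return an \linkS4class{ErpWindowSet} with exactly \code{n} windows.
#' @export
resampleWindows <- function(ws, n = 200, seed = 1L) {
  if (!nWindows(ws)) stop("cannot resample an empty window set")
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  idx <- sample.int(nWindows(ws), n, replace = TRUE)
  out <- new("ErpWindowSet",
    windows = ws@windows[idx, , drop = FALSE], relTime = ws@relTime,
    condition = ws@condition, region = ws@region,
    sourceTimes = ws@sourceTimes[idx], fs = ws@fs
  )
  attr(out, "sourceIndices") <- idx
  out
}
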