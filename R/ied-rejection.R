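#' Detect interictal discharges by normalized template matching
#'
#' Slides each unit-RMS template along each channel and computes the Pearson
#' correlation between the template and every equal-length signal slice
#' (running-sum implementation). Local maxima of the correlation series
#' exceeding \code{rThreshold} are emitted as detections; detections closer
#' together than one template length are merged, keeping the higher score.
#' Matching is one-sided (positive correlation) by default.
#'
#' @param rec a \linkS4class{Recording}; its rate must match the templates'.
#' @param templates list of \linkS4class{IedTemplate}s (or a single one).
#' @param rThreshold correlation threshold in (0, 1] (default 0.8).
#' @param twoSided if TRUE, match on |r| (detects sign-flipped spikes).
#' @return data.frame with columns channel, time_s (template center), score,
#'   template.
#' @export
detectIeds <- function(rec, templates, rThreshold = 0.8, twoSided = FALSE) {
  if (is(templates, "IedTemplate")) templates <- list(templates)
  if (rThreshold <= 0 || rThreshold > 1) stop("rThreshold must be in (0, 1]")
  out <- list()
  for (tpl in templates) {
    if (abs(tpl@fs - rec@fs) > 1e-9)
      stop(sprintf("template rate (%g) != recording rate (%g)", tpl@fs, rec@fs))
    L <- length(tpl@waveform)
    if (L > ncol(rec@data)) stop("template longer than recording")
    tz <- tpl@waveform - mean(tpl@waveform)
    sst <- sum(tz^2)
    for (ch in seq_len(nChannels(rec))) {
      x <- rec@data[ch, ]
      r <- .slidingPearson(x, tz, sst, L)
      score <- if (twoSided) abs(r) else r
      n <- length(score)
      if (n < 3L) next
      peaks <- which(score[2:(n - 1)] > score[1:(n - 2)] &
                     score[2:(n - 1)] >= score[3:n] &
                     score[2:(n - 1)] > rThreshold) + 1L
      # include a flat-top perfect match at the boundary of numeric equality
      if (!length(peaks)) next
      for (p in peaks) {
        out[[length(out) + 1L]] <- data.frame(
          channel = rec@channelLabels[ch],
          time_s = (p - 1 + (L - 1) / 2) / rec@fs,
          score = r[p], template = tpl@name, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out))
    return(data.frame(
      channel = character(0), time_s = numeric(0),
      score = numeric(0), template = character(0)
    ))
  det <- do.call(rbind, out)
  # merge detections closer than one template length, higher score wins
  Lsec <- max(vapply(templates, function(t) length(t@waveform), 1L)) / rec@fs
  merged <- list()
  for (chn in unique(det$channel)) {
    d <- det[det$channel == chn, , drop = FALSE]
    d <- d[order(-abs(d$score), d$time_s), , drop = FALSE]
    kept <- d[0, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (!nrow(kept) || all(abs(kept$time_s - d$time_s[i]) >= Lsec))
        kept <- rbind(kept, d[i, , drop = FALSE])
    }
    merged[[chn]] <- kept
  }
  det <- do.call(rbind, merged)
  det <- det[order(det$time_s, det$channel), , drop = FALSE]
  rownames(det) <- NULL
  det
}

# Pearson r between the (mean-centered) template tz and every length-L slice
# of x, via running sums; returns a series of length(x) - L + 1.
.slidingPearson <- function(x, tz, sst, L) {
  n <- length(x)
  nw <- n - L + 1L
  # sliding dot product of x with tz
  dot <- as.numeric(stats::filter(x, rev(tz), method = "convolution", sides = 1))[L:n]
  c1 <- c(0, cumsum(x))
  c2 <- c(0, cumsum(x^2))
  s1 <- c1[(L + 1):(n + 1)] - c1[1:nw]
  s2 <- c2[(L + 1):(n + 1)] - c2[1:nw]
  ssx <- pmax(s2 - s1^2 / L, 0)
  denom <- sqrt(ssx * sst)
  r <- ifelse(denom > 0, dot / denom, 0)
  pmin(pmax(r, -1), 1)
}

#' Reject windows containing an interictal discharge
#'
#' A window is rejected iff any detection on any channel, expanded to the
#' template's temporal extent, intersects the window's absolute time span.
#' Rejection acts on the per-channel window stack, before region averaging
#' and before bootstrap resampling, so rejected windows can never re-enter.
#'
#' @param arr an \linkS4class{ErpWindowArray}.
#' @param detections data.frame from \code{\link{detectIeds}}.
#' @param templateDurationS temporal extent of a detection, seconds
#'   (default 0.25, the default template length).
#' @return list with \code{windows} (the reduced
#'   \linkS4class{ErpWindowArray}) and \code{nRejected}.
#' @export
rejectWindows <- function(arr, detections, templateDurationS = 0.25) {
  pre <- -min(arr@relTime)
  post <- max(arr@relTime)
  lo <- arr@sourceTimes - pre
  hi <- arr@sourceTimes + post
  half <- templateDurationS / 2
  bad <- rep(FALSE, length(lo))
  for (td in detections$time_s) {
    bad <- bad | (hi > td - half & lo < td + half)
  }
  if (all(bad))
    stop(sprintf(
      "all %d '%s' windows rejected by IED detections", length(bad), arr@condition
    ))
  out <- new("ErpWindowArray",
    windows = arr@windows[!bad, , , drop = FALSE], relTime = arr@relTime,
    condition = arr@condition, sourceTimes = arr@sourceTimes[!bad],
    fs = arr@fs, channelLabels = arr@channelLabels,
    channelRegions = arr@channelRegions
  )
  list(windows = out, nRejected = sum(bad))
}
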