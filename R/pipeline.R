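#' Full pipeline configuration
#'
#' Nested configuration mirroring each stage: \code{preprocess}
#' (\code{\link{preprocessConfig}}), \code{segmentation}
#' (\code{\link{segmentationConfig}}), \code{ied} (rThreshold, twoSided),
#' \code{stats} (\code{\link{clusterTestConfig}}) and \code{integration}
#' (nLight, nDark), plus a global \code{seed} from which all stage seeds are
#' derived.
#'
#' @param preprocess,segmentation,ied,stats,integration stage configs.
#' @param seed global RNG seed.
#' @return nested config list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(preprocess = preprocessConfig(),
                           segmentation = segmentationConfig(),
                           ied = list(rThreshold = 0.8, twoSided = FALSE),
                           stats = clusterTestConfig(),
                           integration = list(nLight = 6, nDark = 10),
                           seed = 1L) {
  cfg <- list(
    preprocess = preprocess, segmentation = segmentation, ied = ied,
    stats = stats, integration = integration, seed = as.integer(seed)
  )
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

.comparisons <- function() {
  list(
    note_vs_reference = c("note_onset", "reference"),
    phrase_vs_reference = c("phrase_boundary", "reference"),
    phrase_vs_note = c("phrase_boundary", "note_onset")
  )
}

#' Run the within-session analysis end to end
#'
#' Executes, in order: bad-channel exclusion, filtering / re-referencing /
#' decimation, peri-stimulus segmentation for note onsets and phrase
#' boundaries, reference-window sampling, IED detection and window
#' rejection, region averaging, bootstrap resampling to a fixed window
#' count, and the cluster-level permutation test for the three comparisons
#' (note vs reference, phrase vs reference, phrase vs note) in every
#' subregion.
#'
#' @param rec a raw \linkS4class{Recording}.
#' @param noteOnsets,phraseBoundaries \linkS4class{MarkerTrack}s.
#' @param config a \code{\link{pipelineConfig}}.
#' @param iedTemplates list of \linkS4class{IedTemplate}s at the
#'   preprocessed rate, or NULL to use \code{\link{defaultIedTemplate}}.
#' @param comparisons subset of \code{c("note_vs_reference",
#'   "phrase_vs_reference", "phrase_vs_note")}.
#' @param regions subregions to analyse (default: all in the recording).
#' @return list with \code{results} (comparison -> region ->
#'   \linkS4class{ClusterTestResult}), \code{counts} (window bookkeeping per
#'   stage) and \code{excludedChannels}.
#' @export
runSession <- function(rec, noteOnsets, phraseBoundaries,
                       config = pipelineConfig(), iedTemplates = NULL,
                       comparisons = names(.comparisons()),
                       regions = NULL) {
  pc <- config$preprocess
  if (!is.null(pc$bandHiHz) && pc$bandHiHz >= rec@fs / 2)
    stop(sprintf("bandHiHz (%g) must be below Nyquist (%g)", pc$bandHiHz, rec@fs / 2))

  ex <- excludeBadChannels(rec, pc$badChannelK)
  pp <- preprocessRecording(ex$recording, pc)
  if (is.null(regions)) regions <- unique(pp@channelRegions)

  sc <- config$segmentation
  sc$seed <- config$seed
  arrays <- list(
    note_onset = segmentWindows(pp, noteOnsets, sc),
    phrase_boundary = segmentWindows(pp, phraseBoundaries, sc),
    reference = sampleReferenceWindows(pp, noteOnsets, sc)
  )
  counts <- list(segmented = vapply(arrays, nWindows, 1L))

  if (is.null(iedTemplates)) iedTemplates <- list(defaultIedTemplate(pp@fs))
  detections <- detectIeds(pp, iedTemplates,
    rThreshold = config$ied$rThreshold, twoSided = isTRUE(config$ied$twoSided)
  )
  tplDur <- max(vapply(iedTemplates, function(t) length(t@waveform), 1L)) / pp@fs
  nRej <- integer(0)
  for (k in names(arrays)) {
    rj <- rejectWindows(arrays[[k]], detections, tplDur)
    arrays[[k]] <- rj$windows
    nRej[k] <- rj$nRejected
  }
  counts$iedDetections <- nrow(detections)
  counts$rejected <- nRej
  counts$afterRejection <- vapply(arrays, nWindows, 1L)

  byRegion <- lapply(arrays, averageByRegion, regions = regions)
  counts$resampledTo <- sc$resampleN

  st <- config$stats
  results <- list()
  for (cmp in comparisons) {
    pair <- .comparisons()[[cmp]]
    results[[cmp]] <- list()
    for (rg in names(byRegion[[pair[1]]])) {
      if (is.null(byRegion[[pair[2]]][[rg]])) next
      st$seed <- config$seed + 101L * match(cmp, names(.comparisons())) +
        match(rg, regions)
      results[[cmp]][[rg]] <- clusterPermutationTest(
        byRegion[[pair[1]]][[rg]], byRegion[[pair[2]]][[rg]], st,
        resampleTo = sc$resampleN
      )
    }
  }
  list(results = results, counts = counts, excludedChannels = ex$excluded,
       sessionId = rec@sessionId)
}

#' Run a multi-session study and integrate the results
#'
#' Runs \code{\link{runSession}} on each synthetic session spec (statistics
#' stay within-session), then integrates across sessions: significant-
#' session counts per timepoint, shading intervals, and per-subregion
#' cluster summary tables, per comparison.
#'
#' @param sessionSpecs list of \code{\link{syntheticSessionSpec}}s, or a
#'   list of lists \code{list(recording =, noteOnsets =,
#'   phraseBoundaries =)}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param comparisons comparisons to run (default all three).
#' @param regions subregions to integrate (default: those present in every
#'   session's results).
#' @return list with \code{sessions} (per-session result bundles) and
#'   \code{integration} (comparison -> \linkS4class{IntegrationResult}).
#' @export
runStudy <- function(sessionSpecs, config = pipelineConfig(),
                     comparisons = names(.comparisons()), regions = NULL) {
  if (!length(sessionSpecs)) stop("need at least one session")
  sessions <- vector("list", length(sessionSpecs))
  failed <- character(0)
  for (i in seq_along(sessionSpecs)) {
    sp <- sessionSpecs[[i]]
    sess <- if (inherits(sp, "SyntheticSessionSpec")) generateSession(sp) else sp
    cfgI <- config
    cfgI$seed <- config$seed + i
    res <- tryCatch(
      runSession(sess$recording, sess$noteOnsets, sess$phraseBoundaries,
        cfgI, comparisons = comparisons, regions = regions
      ),
      error = function(e) {
        warning(sprintf("session %d failed: %s", i, conditionMessage(e)))
        NULL
      }
    )
    # assigning NULL into a list would delete the slot; only store successes
    if (is.null(res)) failed <- c(failed, as.character(i))
    else sessions[[i]] <- res
  }
  ok <- sessions[!vapply(sessions, is.null, TRUE)]
  if (!length(ok)) stop("all sessions failed")

  integration <- list()
  for (cmp in comparisons) {
    regionsHere <- Reduce(intersect, lapply(ok, function(s) names(s$results[[cmp]])))
    byRegion <- lapply(regionsHere, function(rg) {
      lapply(ok, function(s) s$results[[cmp]][[rg]])
    })
    names(byRegion) <- regionsHere
    integration[[cmp]] <- integrateSessions(byRegion,
      nLight = config$integration$nLight, nDark = config$integration$nDark
    )
  }
  list(sessions = sessions, integration = integration, failedSessions = failed)
}
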