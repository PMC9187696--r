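#' Cluster permutation test configuration
#'
#' @param alphaForming two-sided per-timepoint p for the cluster-forming
#'   threshold (0.05, i.e. |Z| > 1.96).
#' @param alphaCluster cluster-level significance level (0.05).
#' @param nPermutations number of label permutations (1000; at least 100).
#' @param tieCorrection use the tie-corrected Mann-Whitney variance (TRUE).
#' @param seed RNG seed for the permutations.
#' @return validated config list.
#' @export
clusterTestConfig <- function(alphaForming = 0.05, alphaCluster = 0.05,
                              nPermutations = 1000, tieCorrection = TRUE,
                              seed = 1L) {
  if (alphaForming <= 0 || alphaForming >= 1) stop("alphaForming must be in (0, 1)")
  if (alphaCluster <= 0 || alphaCluster >= 1) stop("alphaCluster must be in (0, 1)")
  if (nPermutations < 100) stop("nPermutations must be at least 100")
  list(
    alphaForming = alphaForming, alphaCluster = alphaCluster,
    nPermutations = as.integer(nPermutations),
    tieCorrection = isTRUE(tieCorrection), seed = as.integer(seed)
  )
}

#' Select a normality test by sample size
#'
#' The D'Agostino-Pearson omnibus test needs a moderately large sample for
#' its skewness/kurtosis normal approximations (the conventional floor is
#' n = 20); below that the Shapiro-Wilk test is used. The pipeline applies
#' the former to the many note-onset and reference windows and the latter to
#' the few phrase-boundary windows.
#'
#' @param n sample count (>= 3).
#' @return \code{"dagostino_pearson"} or \code{"shapiro_wilk"}.
#' @export
chooseNormalityTest <- function(n) {
  if (n < 3) stop("normality testing needs at least 3 observations")
  if (n >= 20) "dagostino_pearson" else "shapiro_wilk"
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness Z and the Anscombe-Glynn kurtosis Z into
#' K2 = Zs^2 + Zk^2, referred to a chi-squared distribution with 2 df.
#'
#' @param x numeric sample (n >= 8 for the kurtosis approximation).
#' @return list with \code{statistic} (K2) and \code{p.value}.
#' @export
dagostinoPearsonTest <- function(x) {
  n <- length(x)
  if (n < 8) stop("dagostinoPearsonTest needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(list(statistic = Inf, p.value = 0))
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  # skewness: D'Agostino (1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Zk <- ((1 - 2 / (9 * A)) -
    ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) / sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  list(statistic = K2, p.value = pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Per-timepoint normality diagnostics of two window sets
#'
#' Applies the sample-size-appropriate normality test to each set's values
#' at every timepoint. Purely diagnostic: the pipeline always proceeds with
#' the rank test, this records how non-Gaussian the data are. A timepoint
#' with (near-)constant values, where the tests are undefined, is flagged
#' non-normal by convention.
#'
#' @param wsA,wsB \linkS4class{ErpWindowSet}s.
#' @param alpha per-test level (0.05).
#' @return list with logical vectors \code{flagsA}, \code{flagsB}
#'   (TRUE = non-normal) and the overall \code{fractionNonNormal}.
#' @export
assessNormality <- function(wsA, wsB, alpha = 0.05) {
  testCol <- function(v) {
    if (length(unique(v)) < 3L) return(TRUE)
    id <- chooseNormalityTest(length(v))
    p <- tryCatch(
      if (id == "dagostino_pearson") dagostinoPearsonTest(v)$p.value
      else shapiro.test(v)$p.value,
      error = function(e) 0
    )
    p < alpha
  }
  fA <- apply(wsA@windows, 2, testCol)
  fB <- apply(wsB@windows, 2, testCol)
  list(
    flagsA = fA, flagsB = fB,
    fractionNonNormal = mean(c(fA, fB))
  )
}

#' Mann-Whitney U and its normal-approximation Z
#'
#' U counts the pairs (x_i, y_j) with x_i > y_j, plus half the tied pairs.
#' Z = (U - n1 n2 / 2) / sigma with the tie-corrected variance
#' sigma^2 = n1 n2 / 12 * (n + 1 - sum(t^3 - t) / (n (n - 1))) when
#' \code{tieCorrection} is on. The sign is retained: positive Z means x is
#' stochastically larger than y. If every value is identical, Z is 0.
#'
#' @param x,y numeric samples of size >= 2.
#' @param tieCorrection use tie-corrected variance (TRUE).
#' @return named numeric vector c(U =, Z =).
#' @export
mannWhitneyZ <- function(x, y, tieCorrection = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 observations")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (tieCorrection) {
    t <- table(pooled)
    tieTerm <- sum(t^3 - t) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tieTerm)
  } else {
    v <- n1 * n2 * (n + 1) / 12
  }
  Z <- if (v <= 0) 0 else (U - n1 * n2 / 2) / sqrt(v)
  c(U = U, Z = Z)
}

#' Two-sided standard-normal critical value
#'
#' @param alphaTwoSided two-sided level in (0, 1).
#' @return the |Z| cutoff, e.g. 1.959964 for alpha = 0.05.
#' @export
zThreshold <- function(alphaTwoSided) {
  if (alphaTwoSided <= 0 || alphaTwoSided >= 1)
    stop("alpha must be in (0, 1)")
  qnorm(1 - alphaTwoSided / 2)
}

#' Form temporal clusters from a Z series
#'
#' Clusters are maximal runs of consecutive timepoints with |Z| above the
#' threshold and a constant sign; adjacent suprathreshold points of opposite
#' sign start a new cluster. Each cluster carries its sign and its summary
#' statistic, the maximum |Z| inside it.
#'
#' @param zSeries numeric Z per timepoint.
#' @param threshold positive |Z| cutoff.
#' @return data.frame with columns start, end (1-based, inclusive), sign,
#'   stat.
#' @export
formClusters <- function(zSeries, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  state <- sign(zSeries) * (abs(zSeries) > threshold)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0)
  if (!length(keep))
    return(data.frame(
      start = integer(0), end = integer(0),
      sign = numeric(0), stat = numeric(0)
    ))
  data.frame(
    start = starts[keep], end = ends[keep], sign = r$values[keep],
    stat = vapply(keep, function(k) {
      max(abs(zSeries[starts[k]:ends[k]]))
    }, numeric(1))
  )
}

# Per-timepoint U -> Z over a pooled rank matrix for an arbitrary group-A
# index set; the per-timepoint rank matrix and tie-corrected sigmas are
# permutation-invariant and precomputed once.
.zSeriesFromRanks <- function(ranks, idxA, n1, n2, sigma) {
  U <- colSums(ranks[idxA, , drop = FALSE]) - n1 * (n1 + 1) / 2
  z <- (U - n1 * n2 / 2) / sigma
  z[!is.finite(z)] <- 0
  z
}

# Tie-corrected per-timepoint sigmas of U for a pooled value matrix.
.mwSigma <- function(pooled, n1, n2, tieCorrection) {
  n <- n1 + n2
  nT <- ncol(pooled)
  if (tieCorrection) {
    tieTerm <- apply(pooled, 2, function(v) {
      t <- table(v)
      sum(t^3 - t) / (n * (n - 1))
    })
    v <- n1 * n2 / 12 * ((n + 1) - tieTerm)
  } else {
    v <- rep(n1 * n2 * (n + 1) / 12, nT)
  }
  sigma <- sqrt(pmax(v, 0))
  sigma[sigma == 0] <- Inf # Z := 0 at degenerate timepoints
  sigma
}

# Z series for a bootstrap draw described by per-unique-row weights, using a
# precomputed per-column value ordering of the unique pool. Valid when no
# two distinct unique rows tie within a column (checked by the caller):
# U = sum_k wA[k] * (B-weight strictly below k), ties then arise only from
# row duplication and give a column-constant variance correction.
.zSeriesFromWeights <- function(ord, wA, wB, n1, n2, tieCorrection) {
  nU <- length(wA)
  nT <- ncol(ord)
  WA <- matrix(wA[ord], nU, nT)
  WB <- matrix(wB[ord], nU, nT)
  # column-wise cumsum without apply: cumsum the flattened matrix and
  # remove each column's carried-over offset
  v <- cumsum(WB)
  CB <- matrix(v, nU, nT) - rep(c(0, v[seq_len(nT - 1L) * nU]), each = nU)
  U <- colSums(WA * (CB - WB))
  n <- n1 + n2
  if (tieCorrection) {
    cnt <- wA + wB
    tieTerm <- sum(cnt^3 - cnt) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tieTerm)
  } else {
    v <- n1 * n2 * (n + 1) / 12
  }
  if (v <= 0) return(numeric(nT))
  (U - n1 * n2 / 2) / sqrt(v)
}

#' Cluster-level permutation test between two window sets
#'
#' The observed Z series is the per-timepoint Mann-Whitney Z between the two
#' sets; clusters are formed at the two-sided normal threshold for
#' \code{alphaForming}. Under each of \code{nPermutations} permutations the
#' condition labels are shuffled over the pooled source windows (group
#' sizes preserved), the Z series and clusters recomputed, and the
#' permutation summarized by its maximum cluster statistic (0 when no
#' cluster forms) — a max-statistic null that controls familywise error
#' over clusters. Each observed cluster's p-value is the add-one
#' permutation estimate (1 + #\{summaries >= stat\}) / (1 + nPermutations).
#'
#' With \code{resampleTo = n}, both conditions are bootstrap-resampled to
#' \code{n} windows \emph{inside} the test: the observed statistic uses one
#' seeded bootstrap draw per condition, and every permutation first
#' shuffles the condition labels over the pooled \emph{source} windows and
#' then draws its own bootstrap of size \code{n} per group. Observed and
#' permuted statistics then share the same duplication structure, so the
#' null calibration remains exact; resampling the groups once before
#' permuting instead (duplicates concentrated within the observed groups
#' but split by the shuffle) breaks exchangeability and grossly inflates
#' the false-positive rate.
#'
#' @param wsA,wsB \linkS4class{ErpWindowSet}s sharing region, rate and
#'   window length.
#' @param cfg a \code{\link{clusterTestConfig}}.
#' @param resampleTo bootstrap both groups to this window count inside the
#'   test (NULL: use the windows as given).
#' @return a \linkS4class{ClusterTestResult}.
#' @export
clusterPermutationTest <- function(wsA, wsB, cfg = clusterTestConfig(),
                                   resampleTo = NULL) {
  if (ncol(wsA@windows) != ncol(wsB@windows))
    stop("window-length mismatch between conditions")
  if (abs(wsA@fs - wsB@fs) > 1e-9) stop("sampling-rate mismatch")
  nUA <- nrow(wsA@windows); nUB <- nrow(wsB@windows)
  if (nUA < 2 || nUB < 2) stop("each condition needs at least 2 windows")
  nT <- ncol(wsA@windows)
  nU <- nUA + nUB
  pooled <- rbind(wsA@windows, wsB@windows)
  threshold <- zThreshold(cfg$alphaForming)
  set.seed(cfg$seed)

  if (is.null(resampleTo)) {
    n1 <- nUA; n2 <- nUB
    ranks <- apply(pooled, 2, rank)
    sigma <- .mwSigma(pooled, n1, n2, cfg$tieCorrection)
    zObs <- .zSeriesFromRanks(ranks, seq_len(n1), n1, n2, sigma)
    permZ <- function() {
      .zSeriesFromRanks(ranks, sample.int(nU, n1), n1, n2, sigma)
    }
  } else {
    n1 <- n2 <- as.integer(resampleTo)
    crossTies <- any(apply(pooled, 2, anyDuplicated) > 0)
    if (crossTies) {
      # exact but slower path: rank every bootstrap multiset from scratch
      drawZ <- function(rowsA, rowsB) {
        iA <- rowsA[sample.int(length(rowsA), n1, replace = TRUE)]
        iB <- rowsB[sample.int(length(rowsB), n2, replace = TRUE)]
        X <- pooled[c(iA, iB), , drop = FALSE]
        sg <- .mwSigma(X, n1, n2, cfg$tieCorrection)
        .zSeriesFromRanks(apply(X, 2, rank), seq_len(n1), n1, n2, sg)
      }
    } else {
      ord <- apply(pooled, 2, order)
      drawZ <- function(rowsA, rowsB) {
        iA <- rowsA[sample.int(length(rowsA), n1, replace = TRUE)]
        iB <- rowsB[sample.int(length(rowsB), n2, replace = TRUE)]
        .zSeriesFromWeights(ord, tabulate(iA, nU), tabulate(iB, nU),
          n1, n2, cfg$tieCorrection
        )
      }
    }
    zObs <- drawZ(seq_len(nUA), nUA + seq_len(nUB))
    permZ <- function() {
      lab <- sample.int(nU, nUA)
      drawZ(lab, setdiff(seq_len(nU), lab))
    }
  }

  cl <- formClusters(zObs, threshold)
  if (nrow(cl)) {
    permMax <- numeric(cfg$nPermutations)
    for (b in seq_len(cfg$nPermutations)) {
      cb <- formClusters(permZ(), threshold)
      permMax[b] <- if (nrow(cb)) max(cb$stat) else 0
    }
    cl$p <- vapply(cl$stat, function(s) {
      (1 + sum(permMax >= s)) / (1 + cfg$nPermutations)
    }, numeric(1))
  } else {
    cl$p <- numeric(0)
  }
  cl$significant <- cl$p <= cfg$alphaCluster
  cl$startMs <- 1000 * wsA@relTime[cl$start]
  cl$endMs <- 1000 * wsA@relTime[cl$end]
  cl <- cl[, c("start", "end", "startMs", "endMs", "sign", "stat", "p", "significant"), drop = FALSE]

  new("ClusterTestResult",
    zSeries = zObs, relTime = wsA@relTime, clusters = cl,
    threshold = threshold, nA = as.integer(n1), nB = as.integer(n2),
    conditionA = wsA@condition, conditionB = wsB@condition,
    region = wsA@region
  )
}
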