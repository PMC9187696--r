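# Shared fixtures and independently derived oracles.

# Small two-region session spec: default dense schedule, cheap to analyze.
# Two regions are required: with a single region the average reference
# forces the region-averaged signal to zero identically.
smallSessionSpec <- function(seed, ...) {
  syntheticSessionSpec(
    regionNames = c("superior_temporal", "middle_temporal"),
    nChannelsPerRegion = 2, seed = seed, ...
  )
}

# ERP parameter tables with no injected response (null sessions).
nullErpParams <- function() {
  empty <- data.frame(
    latencyMs = numeric(0), amplitude = numeric(0), widthMs = numeric(0)
  )
  list(note_onset = empty, phrase_boundary = empty)
}

# Brute-force Mann-Whitney U: pairs with x > y plus half the tied pairs.
bruteForceU <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Exact two-sided Mann-Whitney p at small n by full enumeration of all
# choose(n1 + n2, n1) group assignments: P(|U' - mu| >= |U - mu|).
exactMannWhitneyP <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  mu <- n1 * length(y) / 2
  uObs <- bruteForceU(x, y)
  splits <- combn(length(pooled), n1)
  us <- apply(splits, 2, function(idx) {
    bruteForceU(pooled[idx], pooled[-idx])
  })
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# Exhaustive DTW: enumerate every monotone path with steps (1,0), (0,1),
# (1,1) from (1,1) to (n,m) and return the minimal cumulative cost.
exhaustiveDtwCost <- function(a, b) {
  n <- length(a)
  m <- length(b)
  cost <- function(i, j) abs(a[i] - b[j])
  best <- Inf
  recur <- function(i, j, acc) {
    acc <- acc + cost(i, j)
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) recur(i + 1, j + 1, acc)
    if (i < n) recur(i + 1, j, acc)
    if (j < m) recur(i, j + 1, acc)
    invisible()
  }
  recur(1, 1, 0)
  best
}

# ErpWindowSet from a plain windows-by-samples matrix.
windowSet <- function(m, fs = 256, condition = "note_onset",
                      region = "superior_temporal") {
  m <- as.matrix(m)
  pre <- floor((ncol(m) - 1) / 2)
  relTime <- ((seq_len(ncol(m)) - 1) - pre) / fs
  new("ErpWindowSet",
    windows = m, relTime = relTime, condition = condition,
    region = region, sourceTimes = as.numeric(seq_len(nrow(m))), fs = fs
  )
}

# ClusterTestResult with prescribed clusters, for integration fixtures.
# clusterDf needs columns start, end (1-based sample indices) and p.
resultWithClusters <- function(relTime, clusterDf,
                               region = "superior_temporal",
                               alpha = 0.05) {
  if (nrow(clusterDf)) {
    cl <- data.frame(
      start = as.integer(clusterDf$start), end = as.integer(clusterDf$end),
      startMs = 1000 * relTime[clusterDf$start],
      endMs = 1000 * relTime[clusterDf$end],
      sign = 1, stat = 3, p = clusterDf$p,
      significant = clusterDf$p <= alpha
    )
  } else {
    cl <- data.frame(
      start = integer(0), end = integer(0), startMs = numeric(0),
      endMs = numeric(0), sign = numeric(0), stat = numeric(0),
      p = numeric(0), significant = logical(0)
    )
  }
  new("ClusterTestResult",
    zSeries = numeric(length(relTime)), relTime = relTime, clusters = cl,
    threshold = 1.96, nA = 200L, nB = 200L,
    conditionA = "phrase_boundary", conditionB = "reference", region = region
  )
}
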