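test_that("the Mann-Whitney U statistic equals brute-force pair counting", {
  set.seed(31)
  for (rep in 1:100) {
    n1 <- sample(2:12, 1)
    n2 <- sample(2:12, 1)
    x <- round(rnorm(n1), sample(0:1, 1)) # rounding induces ties
    y <- round(rnorm(n2), sample(0:1, 1))
    expect_equal(unname(mannWhitneyZ(x, y)["U"]), bruteForceU(x, y))
  }
})

test_that("U agrees with stats::wilcox.test and Z carries the direction", {
  set.seed(32)
  x <- rnorm(10, 1)
  y <- rnorm(8)
  expect_equal(
    unname(mannWhitneyZ(x, y)["U"]),
    unname(suppressWarnings(wilcox.test(x, y))$statistic)
  )
  expect_gt(mannWhitneyZ(x, y)["Z"], 0)
  expect_lt(mannWhitneyZ(y, x)["Z"], 0)
  expect_equal(unname(mannWhitneyZ(rep(1, 5), rep(1, 5))["Z"]), 0)
})

test_that("tie-corrected variance matches the analytic formula", {
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 3, 4)
  got <- mannWhitneyZ(x, y, tieCorrection = TRUE)
  n <- 8
  t <- c(1, 3, 3, 1) # multiplicities of values 1, 2, 3, 4
  v <- 4 * 4 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
  expect_equal(unname(got["Z"]), (unname(got["U"]) - 8) / sqrt(v))
})

test_that("normality testing: size-based selection and calibration", {
  expect_equal(chooseNormalityTest(19), "shapiro_wilk")
  expect_equal(chooseNormalityTest(20), "dagostino_pearson")
  expect_error(chooseNormalityTest(2), "at least 3")
  set.seed(33)
  gauss <- rnorm(500)
  skewed <- rexp(500)^2
  expect_gt(dagostinoPearsonTest(gauss)$p.value, 0.01)
  expect_lt(dagostinoPearsonTest(skewed)$p.value, 1e-10)
  expect_error(dagostinoPearsonTest(rnorm(5)), "n >= 8")
})

test_that("normality assessment flags constant and non-Gaussian timepoints", {
  set.seed(34)
  m <- matrix(rnorm(30 * 6), 30, 6)
  m[, 3] <- 0 # constant -> flagged by convention
  m[, 5] <- rexp(30)^3 # grossly non-Gaussian
  out <- assessNormality(windowSet(m), windowSet(matrix(rnorm(30 * 6), 30)))
  expect_true(out$flagsA[3])
  expect_true(out$flagsA[5])
  expect_length(out$flagsB, 6)
  expect_true(out$fractionNonNormal >= 0 && out$fractionNonNormal <= 1)
})

test_that("cluster forming splits runs at threshold crossings and sign flips", {
  z <- c(0, 2.5, 2.6, 0, -3, -2.2, 2.1, 0)
  cl <- formClusters(z, 1.96)
  expect_equal(cl$start, c(2, 5, 7))
  expect_equal(cl$end, c(3, 6, 7))
  expect_equal(cl$sign, c(1, -1, 1))
  expect_equal(cl$stat, c(2.6, 3, 2.1))
  # adjacent suprathreshold samples of opposite sign are distinct clusters
  cl2 <- formClusters(c(2.5, -2.5), 1.96)
  expect_equal(nrow(cl2), 2)
  expect_equal(nrow(formClusters(c(0, 1, -1.5), 1.96)), 0)
})

test_that("a strong localized shift yields one significant cluster over its extent", {
  set.seed(35)
  nT <- 60
  a <- matrix(rnorm(40 * nT), 40, nT)
  b <- matrix(rnorm(40 * nT), 40, nT)
  a[, 21:30] <- a[, 21:30] + 2.5
  res <- clusterPermutationTest(
    windowSet(a), windowSet(b),
    clusterTestConfig(nPermutations = 200, seed = 1)
  )
  sig <- clusters(res, significantOnly = TRUE)
  expect_equal(nrow(sig), 1)
  expect_lte(abs(sig$start - 21), 1)
  expect_lte(abs(sig$end - 30), 1)
  expect_equal(sig$sign, 1)
  expect_equal(sig$p, 1 / 201) # nothing in the null reaches it
})

test_that("the bootstrap-weighted Z equals the explicit Z on the expanded draw", {
  set.seed(36)
  pooled <- matrix(rnorm(12 * 9), 12, 9) # no cross-row ties
  ord <- apply(pooled, 2, order)
  # the fast path assumes the two groups bootstrap disjoint source rows,
  # which the permutation test guarantees by construction
  iA <- sample(1:6, 20, replace = TRUE)
  iB <- sample(7:12, 20, replace = TRUE)
  fast <- ieegerp:::.zSeriesFromWeights(
    ord, tabulate(iA, 12), tabulate(iB, 12), 20, 20, TRUE
  )
  slow <- vapply(1:9, function(j) {
    unname(mannWhitneyZ(pooled[iA, j], pooled[iB, j])["Z"])
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("permutation p-values respect the add-one floor and input checks fire", {
  ws <- windowSet(matrix(rnorm(10 * 5), 10, 5))
  res <- clusterPermutationTest(ws, windowSet(matrix(rnorm(10 * 5) + 50, 10, 5)),
    clusterTestConfig(nPermutations = 100, seed = 2)
  )
  cl <- clusters(res)
  expect_true(all(cl$p >= 1 / 101))
  expect_error(
    clusterPermutationTest(ws, windowSet(matrix(0, 5, 4))),
    "length mismatch"
  )
  expect_error(clusterTestConfig(nPermutations = 50), "at least 100")
  expect_error(zThreshold(0), "in \\(0, 1\\)")
})
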