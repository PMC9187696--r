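test_that("significance counts accumulate cluster coverage per timepoint", {
  relTime <- (0:9) / 256
  res <- list(
    resultWithClusters(relTime, data.frame(start = 2, end = 5, p = 0.01)),
    resultWithClusters(relTime, data.frame(start = 4, end = 8, p = 0.02)),
    # non-significant cluster: contributes nothing
    resultWithClusters(relTime, data.frame(start = 1, end = 10, p = 0.2)),
    # two clusters in one session still count that session once per timepoint
    resultWithClusters(relTime, data.frame(start = c(2, 4), end = c(3, 5),
                                           p = c(0.03, 0.04)))
  )
  expect_equal(
    significanceCounts(res),
    c(0, 2, 2, 3, 3, 1, 1, 1, 0, 0)
  )
  expect_error(
    significanceCounts(list(res[[1]], resultWithClusters((0:5) / 256, res[[1]]@clusters[0, ]))),
    "time axis"
  )
})

test_that("shading intervals nest dark within light at the two thresholds", {
  relTime <- (0:9) / 100
  counts <- c(0, 2, 2, 3, 3, 3, 2, 0, 2, 2)
  sh <- shadingIntervals(counts, relTime, nLight = 2, nDark = 3)
  light <- sh[sh$level == "light", ]
  dark <- sh[sh$level == "dark", ]
  expect_equal(light$startMs, c(10, 80))
  expect_equal(light$endMs, c(60, 90))
  expect_equal(dark$startMs, 30)
  expect_equal(dark$endMs, 50)
  for (i in seq_len(nrow(dark))) {
    expect_true(any(light$startMs <= dark$startMs[i] & light$endMs >= dark$endMs[i]))
  }
  none <- shadingIntervals(c(0, 0), (0:1) / 100, 2, 3)
  expect_equal(nrow(none), 0)
})

test_that("the summary table reports exact count / mean / population-SD arithmetic", {
  relTime <- (0:9) / 256
  byRegion <- list(
    superior_temporal = list(
      resultWithClusters(relTime, data.frame(start = 1, end = 3, p = 0.01)),
      resultWithClusters(relTime, data.frame(start = c(2, 6), end = c(4, 8),
                                             p = c(0.02, 0.03)))
    ),
    insular = list(
      resultWithClusters(relTime, data.frame(start = 1, end = 2, p = 0.5),
                         region = "insular"),
      resultWithClusters(relTime, data.frame(start = integer(0), end = integer(0),
                                             p = numeric(0)), region = "insular")
    )
  )
  tab <- clusterSummaryTable(byRegion)
  st <- tab[tab$region == "superior_temporal", ]
  expect_equal(st$nClusters, 3L)
  expect_equal(st$meanP, round(mean(c(0.01, 0.02, 0.03)), 3))
  expect_equal(st$sdP, round(sqrt(mean((c(0.01, 0.02, 0.03) - 0.02)^2)), 3))
  ins <- tab[tab$region == "insular", ]
  expect_equal(ins$nClusters, 0L)
  expect_true(is.na(ins$meanP) && is.na(ins$sdP))
})

test_that("integrateSessions assembles counts, shading and summary coherently", {
  relTime <- (0:9) / 256
  byRegion <- list(
    superior_temporal = lapply(1:3, function(i) {
      resultWithClusters(relTime, data.frame(start = 3, end = 6, p = 0.01))
    })
  )
  out <- integrateSessions(byRegion, nLight = 2, nDark = 3)
  expect_s4_class(out, "IntegrationResult")
  expect_equal(out@nSessions, 3L)
  expect_equal(unname(out@counts["superior_temporal", ]),
               c(0, 0, 3, 3, 3, 3, 0, 0, 0, 0))
  sh <- out@shading$superior_temporal
  expect_equal(sh[sh$level == "dark", ]$startMs, 1000 * relTime[3])
  expect_equal(out@summary$nClusters, 3L)
  expect_error(integrateSessions(list()), "no regions")
})
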