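test_that("column normalisation yields zero-mean unit-sd columns", {
  set.seed(91)
  mats <- array(rnorm(4 * 6 * 6, mean = 3, sd = 2), c(4, 6, 6))
  z <- normalizeConnectivity(mats)
  for (s in 1:4) for (j in 1:6) {
    expect_lt(abs(mean(z[s, , j])), 1e-10)
    expect_lt(abs(sd(z[s, , j]) - 1), 1e-10)
  }
  mm <- normalizeConnectivity(mats, "minmax")
  expect_gte(min(mm), 0)
  expect_lte(max(mm), 1)
})

test_that("group means equal the per-subject loop average", {
  set.seed(92)
  S <- 10L; N <- 5L
  mats <- array(rnorm(S * N * N), c(S, N, N))
  labels <- rep(c(0L, 1L), each = 5L)
  # loop oracle
  acc <- matrix(0, N, N)
  for (s in which(labels == 1L)) acc <- acc + mats[s, , ]
  m1 <- apply(mats[labels == 1L, , ], c(2, 3), mean)
  expect_equal(m1, acc / 5, tolerance = 1e-12)
  st <- pairwiseGroupTtests(mats, labels, correction = "none")
  expect_equal(st@groupMeans[[2]], m1, tolerance = 1e-12)
  # identical groups give equal means and t = 0, p = 1
  dup <- array(0, c(4, N, N))
  dup[1, , ] <- dup[3, , ] <- mats[1, , ]
  dup[2, , ] <- dup[4, , ] <- mats[2, , ]
  st2 <- pairwiseGroupTtests(dup, c(0L, 0L, 1L, 1L), correction = "none")
  expect_equal(st2@groupMeans[[1]], st2@groupMeans[[2]])
  off <- upper.tri(st2@tStat) | lower.tri(st2@tStat)
  expect_true(all(abs(st2@tStat[off]) < 1e-12 | is.na(st2@tStat[off])))
  expect_true(all(st2@pValue[off] > 0.999999 | is.na(st2@pValue[off])))
})

test_that("an injected mean shift produces the closed-form t statistic", {
  set.seed(93)
  n <- 200L; N <- 10L
  mats <- array(rnorm(2 * n * N * N), c(2 * n, N, N))
  labels <- rep(c(0L, 1L), each = n)
  mats[labels == 1L, 3, 7] <- mats[labels == 1L, 3, 7] + 1
  st <- pairwiseGroupTtests(mats, labels, alpha = 0.05,
                            correction = "bonferroni")
  tExp <- 1 / sqrt(2 / n) # Delta / sqrt(2 sigma^2 / n) with sigma = 1
  expect_lt(abs(st@tStat[3, 7] - tExp) / tExp, 0.2)
  expect_true(st@sigMask[3, 7])
  # the Bonferroni mask is a subset of the uncorrected mask
  stU <- pairwiseGroupTtests(mats, labels, alpha = 0.05, correction = "none")
  expect_true(all(!st@sigMask | stU@sigMask))
})

test_that("the null false-positive count stays controlled across 20 seeds", {
  # two groups from the identical distribution; a Bonferroni-corrected 0.01
  # level keeps the expected total count across 20 replicates at 0.2
  N <- 8L
  fp <- 0L
  for (seed in 1:20) {
    set.seed(seed + 900L)
    mats <- array(rnorm(40 * N * N), c(40, N, N))
    st <- pairwiseGroupTtests(mats, rep(c(0L, 1L), each = 20L),
                              alpha = 0.01, correction = "bonferroni")
    fp <- fp + sum(st@sigMask, na.rm = TRUE)
  }
  expect_lte(fp, 1L)
})

test_that("network summaries count distinct significant nodes", {
  map <- networkMap(c(1, 1, 1, 2, 2, 3, 3, 3))
  tS <- matrix(0, 8, 8)
  pV <- matrix(1, 8, 8)
  mask <- matrix(FALSE, 8, 8)
  st <- new("GroupFcStats", groupMeans = list(tS, tS), tStat = tS,
            pValue = pV, sigMask = mask, alpha = 0.05,
            correction = "bonferroni", nTests = 56L)
  expect_equal(unname(networkSummary(st, map)), c(0L, 0L, 0L))
  mask[1, 2] <- mask[2, 3] <- TRUE # pairs among ROIs 1..3 of network 1
  st@sigMask <- mask
  expect_equal(unname(networkSummary(st, map)), c(3L, 0L, 0L))
})

test_that("zero-variance pairs are reported NA rather than infinite", {
  set.seed(94)
  mats <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  mats[, 2, 3] <- 5 # constant in both groups
  st <- pairwiseGroupTtests(mats, rep(c(0L, 1L), 4L), correction = "none")
  expect_true(is.na(st@tStat[2, 3]))
  expect_true(is.na(st@pValue[2, 3]))
})

test_that("interpretation outputs round-trip to TSV", {
  set.seed(95)
  mats <- array(rnorm(12 * 6 * 6), c(12, 6, 6))
  labels <- rep(c(0L, 1L), each = 6L)
  mats[labels == 1L, 1, 4] <- mats[labels == 1L, 1, 4] + 3
  st <- pairwiseGroupTtests(mats, labels, alpha = 0.05, correction = "none")
  map <- networkMap(rep(1:2, each = 3))
  d <- withr::local_tempdir()
  writeGroupFcStats(st, map, d)
  expect_true(all(file.exists(file.path(d, c("t_matrix.tsv", "p_matrix.tsv",
                                             "significant_pairs.tsv",
                                             "network_counts.tsv")))))
  tm <- readConnectivity(file.path(d, "t_matrix.tsv"))
  expect_equal(unname(tm[1, 4]), st@tStat[1, 4], tolerance = 1e-12)
})
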