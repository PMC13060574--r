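test_that("correlation matches the textbook formula and handles edge cases", {
  set.seed(51)
  X <- matrix(rnorm(40), 4, 10)
  R <- pearsonMatrix(X)
  # oracle: explicit covariance / sigma formula per pair
  for (i in 1:4) for (j in 1:4) {
    num <- mean(X[i, ] * X[j, ]) - mean(X[i, ]) * mean(X[j, ])
    den <- sqrt(mean(X[i, ]^2) - mean(X[i, ])^2) *
      sqrt(mean(X[j, ]^2) - mean(X[j, ])^2)
    expect_lt(abs(R[i, j] - num / den), 1e-10)
  }
  expect_equal(R, cor(t(X)), tolerance = 1e-12, ignore_attr = TRUE)
  same <- rbind(X[1, ], X[1, ])
  expect_equal(pearsonMatrix(same)[1, 2], 1)
  expect_equal(pearsonMatrix(rbind(X[1, ], -X[1, ]))[1, 2], -1)
  expect_warning(Rc <- pearsonMatrix(rbind(X[1, ], rep(2, 10))), "constant")
  expect_equal(Rc[1, 2], 0)
  expect_error(pearsonMatrix(X[, 1, drop = FALSE]), "2 feature columns")
})

test_that("edge retention keeps the exact global top fraction", {
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  # N = 100 study case: ceiling(0.30 * 4950) = 1485 edges
  set.seed(52)
  feats100 <- matrix(rnorm(100 * 40), 100, 40)
  lcFake <- new("LearnedConnectivity",
                attFC = matrix(1 / 100, 100, 100),
                perHead = list())
  g100 <- buildGraph(lcFake, feats100, keepFraction = 0.30)
  expect_equal(nrow(g100@edges), 1485L)
  # exhaustive ranking check on the same instance
  R <- pearsonMatrix(feats100)
  vals <- abs(R[upper.tri(R)])
  thr <- sort(vals, decreasing = TRUE)[1485]
  expect_true(all(abs(g100@edgeWeights) >= thr - 1e-12))
  # complete graph at keepFraction = 1
  featsN <- matrix(rnorm(cfg$nRois * 30), cfg$nRois)
  lc <- learnConnectivity(matrix(rnorm(cfg$nRois * 18), cfg$nRois), params, cfg)
  gAll <- buildGraph(lc, featsN, keepFraction = 1)
  expect_equal(nrow(gAll@edges), cfg$nRois * (cfg$nRois - 1L) / 2L)
  A <- adjacencyMatrix(gAll)
  expect_equal(A, t(A))
  expect_equal(diag(A), rep(0, cfg$nRois))
})

test_that("a 4-node toy matches the brute-force edge ranking", {
  feats <- rbind(c(1, 2, 3, 4, 5),
                 c(1, 2, 3, 4, 6),
                 c(5, 3, 2, 1, 0),
                 c(1, -2, 3, -4, 5))
  lc <- new("LearnedConnectivity", attFC = matrix(1 / 4, 4, 4), perHead = list())
  R <- pearsonMatrix(feats)
  iu <- which(upper.tri(R), arr.ind = TRUE)
  ord <- order(-abs(R[upper.tri(R)]), iu[, 1], iu[, 2])
  for (kf in c(0.2, 0.5, 0.9)) {
    m <- ceiling(kf * 6)
    keep <- sort(ord[seq_len(m)])
    g <- buildGraph(lc, feats, keepFraction = kf)
    expect_equal(nrow(g@edges), m)
    expect_setequal(paste(g@edges[, 1], g@edges[, 2]),
                    paste(iu[keep, 1], iu[keep, 2]))
  }
  # ceiling rule: any positive fraction keeps at least one edge
  expect_equal(nrow(buildGraph(lc, feats, keepFraction = 1e-9)@edges), 1L)
})

test_that("graphs are equivariant under joint node permutation", {
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  set.seed(53)
  sel <- matrix(rnorm(cfg$nRois * 18), cfg$nRois)
  feats <- matrix(rnorm(cfg$nRois * 25), cfg$nRois)
  lc <- learnConnectivity(sel, params, cfg)
  g <- buildGraph(lc, feats, 0.4)
  perm <- sample(cfg$nRois)
  lcp <- learnConnectivity(sel[perm, ], params, cfg)
  gp <- buildGraph(lcp, feats[perm, ], 0.4)
  A <- adjacencyMatrix(g)
  expect_equal(adjacencyMatrix(gp), A[perm, perm], tolerance = 1e-10)
})

test_that("constant-mode edges are stable while dynamic edges track features", {
  co <- tinyCohort()
  cfg <- tinyConfig()
  x <- batchData(co$batch)
  cg <- dsam:::.constantGraphs(x, cfg)
  cg2 <- dsam:::.constantGraphs(x, cfg)
  expect_identical(cg, cg2)
  # dynamic selection changes when the upstream features change
  set.seed(54)
  f1 <- matrix(rnorm(10 * 18), 10)
  f2 <- f1 + matrix(rnorm(10 * 18), 10)
  e1 <- dsam:::.selectEdges(pearsonMatrix(f1), 0.3, "abs")
  e2 <- dsam:::.selectEdges(pearsonMatrix(f2), 0.3, "abs")
  expect_false(identical(e1, e2))
})
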