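rginLayerParams <- function(cfg, din, dout, layer = 1L, seed = 61) {
  # standalone single-layer parameter set for the convolution tests
  set.seed(seed)
  p <- list()
  pre <- sprintf("rgin.l%d", layer)
  p[[paste0(pre, ".th1")]] <- matrix(runif(cfg$nRois * cfg$nClusters), cfg$nRois)
  for (u in seq_len(cfg$nClusters))
    p[[sprintf("%s.bas.u%d", pre, u)]] <- matrix(rnorm(dout * din, 0, 0.3), dout, din)
  p[[paste0(pre, ".bm")]] <- matrix(rnorm(dout * din, 0, 0.1), dout, din)
  p[[paste0(pre, ".eps")]] <- 0.3
  p[[paste0(pre, ".W1")]] <- matrix(rnorm(dout * dout, 0, 0.3), dout, dout)
  p[[paste0(pre, ".b1")]] <- rnorm(dout, 0, 0.1)
  p[[paste0(pre, ".W2")]] <- matrix(rnorm(dout * dout, 0, 0.3), dout, dout)
  p[[paste0(pre, ".b2")]] <- rnorm(dout, 0, 0.1)
  p
}

toyGraph <- function(n = 5L, d = 4L, seed = 62) {
  set.seed(seed)
  H <- matrix(rnorm(n * d), n, d)
  A <- matrix(0, n, n)
  for (k in seq_len(n)) {
    i <- sample(n, 2)
    A[i[1], i[2]] <- A[i[2], i[1]] <- runif(1, -1, 1)
  }
  diag(A) <- 0
  list(nodeFeatures = H, adjacency = A)
}

test_that("K_cl = 1 collapses to a plain shared-basis update", {
  cfg <- dsamConfig(nRois = 5, tPoints = 60, nClusters = 1, dropout = 0)
  g <- toyGraph()
  p <- rginLayerParams(cfg, din = 4L, dout = 3L)
  p[["rgin.l1.th1"]] <- matrix(1, 5, 1) # relu(1) = 1: one shared basis
  got <- rginConv(g, p, layer = 1, nClusters = 1)
  ora <- oracleGinConv(g$nodeFeatures, g$adjacency,
                       W = p[["rgin.l1.bas.u1"]], b = p[["rgin.l1.bm"]],
                       eps = p[["rgin.l1.eps"]],
                       W1 = p[["rgin.l1.W1"]], b1 = p[["rgin.l1.b1"]],
                       W2 = p[["rgin.l1.W2"]], b2 = p[["rgin.l1.b2"]])
  expect_equal(got, ora, tolerance = 1e-10)
})

test_that("without edges the update is the pure self term", {
  cfg <- dsamConfig(nRois = 5, tPoints = 60, nClusters = 3, dropout = 0)
  g <- toyGraph()
  g$adjacency <- matrix(0, 5, 5)
  p <- rginLayerParams(cfg, 4L, 3L)
  got <- rginConv(g, p, layer = 1, nClusters = 3)
  alpha <- pmax(p[["rgin.l1.th1"]][, 1:3], 0)
  for (i in 1:5) {
    Wi <- Reduce(`+`, lapply(1:3, function(u) {
      alpha[i, u] * p[[sprintf("rgin.l1.bas.u%d", u)]]
    })) + p[["rgin.l1.bm"]]
    self <- (1 + p[["rgin.l1.eps"]]) * as.numeric(Wi %*% g$nodeFeatures[i, ])
    h1 <- pmax(self %*% p[["rgin.l1.W1"]] + p[["rgin.l1.b1"]], 0)
    expect_equal(got[i, ], as.numeric(h1 %*% p[["rgin.l1.W2"]] + p[["rgin.l1.b2"]]),
                 tolerance = 1e-10)
  }
})

test_that("the two weight parameterisations agree and assignments are nonnegative", {
  set.seed(63)
  N <- 8L; K <- 7L; dOut <- 3L; dIn <- 5L
  theta1 <- matrix(rnorm(N * K), N, K)
  betas <- lapply(seq_len(K), function(u) matrix(rnorm(dOut * dIn), dOut, dIn))
  theta2 <- vapply(betas, as.numeric, numeric(dOut * dIn))
  b <- matrix(rnorm(dOut * dIn), dOut, dIn)
  for (i in c(1L, 4L, 8L)) {
    expect_equal(rginWeightFromTheta(theta1, theta2, b, i, dOut, dIn),
                 rginWeightFromBases(theta1, betas, b, i), tolerance = 1e-12)
  }
  expect_true(all(pmax(theta1, 0) >= 0))
  # parameter count: K*dout*din + N*K + dout*din, fewer than N full matrices
  expect_equal(rginParamCount(100L, 7L, 100L, 32L),
               7L * 32L * 100L + 100L * 7L + 32L * 100L)
  expect_lt(rginParamCount(100L, 7L, 100L, 32L), 100L * 32L * 100L)
})

test_that("TopK pooling keeps the right nodes with gated features", {
  # 4-node toy, hand-checkable
  H <- rbind(c(2, 0), c(0, 1), c(-1, -1), c(3, 1))
  A <- matrix(0.5, 4, 4); diag(A) <- 0
  omega <- c(1, 0)
  ps <- topkPool(H, A, omega, ratio = 0.5)
  s <- H %*% c(1, 0) # scores 2, 0, -1, 3
  st <- (s - mean(s)) / sqrt(mean((s - mean(s))^2))
  expect_equal(ps$keep, c(1L, 4L))
  expect_equal(ps$scores, as.numeric(st))
  expect_equal(ps$H, (H * as.numeric(1 / (1 + exp(-st))))[c(1, 4), ])
  expect_equal(ps$adjacency, A[c(1, 4), c(1, 4)])
  # scale invariance of the projection
  ps2 <- topkPool(H, A, omega * 17, ratio = 0.5)
  expect_equal(ps2$scores, ps$scores, tolerance = 1e-12)
  # ceiling rule and degenerate equal scores
  expect_length(topkPool(H, A, c(0, 1), ratio = 0.6)$keep, 3L)
  psEq <- topkPool(matrix(1, 4, 2), A, c(1, 1), ratio = 0.5)
  expect_equal(psEq$scores, rep(0, 4))
  expect_equal(psEq$keep, c(1L, 2L)) # lowest indices kept
  expect_error(topkPool(H, A, c(0, 0), 0.5), "nonzero")
  # N = 100 with ratio 0.5 keeps exactly 50
  set.seed(64)
  H100 <- matrix(rnorm(100 * 4), 100)
  expect_length(topkPool(H100, matrix(0, 100, 100), rnorm(4), 0.5)$keep, 50L)
})

test_that("readout concatenates per-layer mean and max summaries", {
  one <- matrix(c(1, 2, 3), 1)
  expect_equal(readoutGraph(list(one)), c(1, 2, 3, 1, 2, 3))
  v <- c(2, -1, 4)
  two <- rbind(v, -v)
  expect_equal(readoutGraph(list(two)), c(rep(0, 3), abs(v)))
  set.seed(65)
  H1 <- matrix(rnorm(15), 5, 3)
  H2 <- matrix(rnorm(8), 2, 4)
  got <- readoutGraph(list(H1, H2))
  ora <- c(vapply(1:3, function(j) mean(H1[, j]), 0),
           vapply(1:3, function(j) max(H1[, j]), 0),
           vapply(1:4, function(j) mean(H2[, j]), 0),
           vapply(1:4, function(j) max(H2[, j]), 0))
  expect_equal(got, ora, tolerance = 1e-12)
  expect_length(got, 2 * 3 + 2 * 4)
  expect_error(readoutGraph(list()), "at least one layer")
})

test_that("the head produces finite two-class logits with softmax summing to 1", {
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  set.seed(66)
  emb <- rnorm(2 * sum(cfg$rginDims))
  lg <- classifyEmbedding(emb, params)
  expect_length(lg, 2L)
  expect_true(all(is.finite(lg)))
  p <- exp(lg - max(lg)); p <- p / sum(p)
  expect_equal(sum(p), 1)
})

test_that("relabeling nodes with their assignments leaves logits unchanged", {
  co <- tinyCohort()
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  x <- batchData(co$batch)
  N <- cfg$nRois
  set.seed(67)
  perm <- sample(N)
  # permute the ROI-indexed parameters together with the data
  pp <- params
  pp[["tatt.WQ"]] <- params[["tatt.WQ"]][perm, , drop = FALSE]
  pp[["tatt.WK"]] <- params[["tatt.WK"]][perm, , drop = FALSE]
  pp[["tatt.WV"]] <- params[["tatt.WV"]][perm, perm]
  pp[["tatt.g"]] <- params[["tatt.g"]][perm]
  pp[["tatt.be"]] <- params[["tatt.be"]][perm]
  pp[["rgin.l1.th1"]] <- params[["rgin.l1.th1"]][perm, , drop = FALSE]
  pp[["rgin.l2.th1"]] <- params[["rgin.l2.th1"]][perm, , drop = FALSE]
  for (u in seq_len(cfg$nClusters)) {
    nm <- sprintf("rgin.l1.bas.u%d", u)
    pp[[nm]] <- params[[nm]][, perm, drop = FALSE] # layer-1 input dim is ROI-indexed
  }
  pp[["rgin.l1.bm"]] <- params[["rgin.l1.bm"]][, perm, drop = FALSE]
  xp <- x[, perm, , drop = FALSE]
  lossBase <- endToEndGrads(params, cfg, x, co$labels, 1:4)
  lossPerm <- endToEndGrads(pp, cfg, xp, co$labels, 1:4)
  l0 <- dsam:::tVal(lossBase$tp, lossBase$fwd$logits)
  l1 <- dsam:::tVal(lossPerm$tp, lossPerm$fwd$logits)
  expect_equal(l1, l0, tolerance = 1e-8)
})
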