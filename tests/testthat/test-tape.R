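# Finite-difference validation of the reverse-mode tape: every backward rule
# used by the model is checked against central differences on random inputs.

fdCheck <- function(buildLoss, x0, h = 1e-6, tol = 1e-6) {
  tp <- dsam:::tapeNew(training = FALSE)
  xid <- dsam:::tParam(tp, "x", x0)
  root <- buildLoss(tp, xid)
  gr <- dsam:::tapeBackward(tp, root)
  g <- dsam:::tapeParamGrads(tp, gr)$x
  set.seed(7)
  for (k in sample(length(x0), min(5L, length(x0)))) {
    xp <- x0; xp[k] <- xp[k] + h
    xm <- x0; xm[k] <- xm[k] - h
    fp <- local({
      tp2 <- dsam:::tapeNew(training = FALSE)
      dsam:::tVal(tp2, buildLoss(tp2, dsam:::tParam(tp2, "x", xp)))
    })
    fm <- local({
      tp2 <- dsam:::tapeNew(training = FALSE)
      dsam:::tVal(tp2, buildLoss(tp2, dsam:::tParam(tp2, "x", xm)))
    })
    fd <- (fp - fm) / (2 * h)
    expect_equal(g[k], fd, tolerance = tol,
                 label = sprintf("analytic grad element %d", k))
  }
}

test_that("elementary op gradients match central differences", {
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  w <- rnorm(6)
  fdCheck(function(tp, x) {
    dsam:::tSum(tp, dsam:::tMatmul(tp, x, dsam:::tConst(tp, B)))
  }, A)
  fdCheck(function(tp, x) {
    y <- dsam:::tSoftmaxRows(tp, x)
    dsam:::tSum(tp, dsam:::tMul(tp, y, y))
  }, A)
  fdCheck(function(tp, x) {
    dsam:::tSum(tp, dsam:::tSigmoid(tp, dsam:::tRelu(tp, x)))
  }, A)
  fdCheck(function(tp, x) {
    dsam:::tSqDev1(tp, dsam:::tVnorm(tp, x))
  }, w)
  fdCheck(function(tp, x) {
    s <- dsam:::tZnormVec(tp, dsam:::tMatmul(tp, x, dsam:::tConst(tp, B[, 1, drop = FALSE])))
    dsam:::tSum(tp, dsam:::tMul(tp, s, s))
  }, A)
})

test_that("correlation, outer-division and gather gradients are exact", {
  set.seed(2)
  X <- matrix(rnorm(40), 5, 8)
  fdCheck(function(tp, x) {
    R <- dsam:::.tPearsonRows(tp, x)
    e <- dsam:::tGather2(tp, R, c(1L, 2L, 4L), c(2L, 3L, 5L))
    A <- dsam:::tScatterSym(tp, e, c(1L, 2L, 4L), c(2L, 3L, 5L), 5L)
    dsam:::tSum(tp, dsam:::tMul(tp, A, A))
  }, X, tol = 1e-5)
})

test_that("reduction and selection gradients are exact", {
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  fdCheck(function(tp, x) {
    m <- dsam:::tColMeansRow(tp, x)
    mx <- dsam:::tColMaxRow(tp, x)
    ro <- dsam:::tCbind(tp, list(m, mx))
    dsam:::tSum(tp, dsam:::tMul(tp, ro, ro))
  }, X)
  fdCheck(function(tp, x) {
    y <- dsam:::tRows(tp, dsam:::tCols(tp, x, c(1L, 3L)), c(2L, 4L, 5L))
    dsam:::tSum(tp, dsam:::tMul(tp, y, y))
  }, X)
})

test_that("the fused norm-rectify kernel matches the composed reference ops", {
  set.seed(19)
  x <- matrix(rnorm(200 * 6), 200, 6)
  gamma <- runif(6, 0.5, 1.5)
  beta <- rnorm(6)
  for (training in c(TRUE, FALSE)) {
    bn1 <- new.env(); bn2 <- new.env()
    bn1$k <- bn2$k <- list(rm = rnorm(6, 0, 0.1), rv = runif(6, 0.5, 2))
    tp <- dsam:::tapeNew(training = training)
    a <- dsam:::tConst(tp, x)
    g1 <- dsam:::tConst(tp, gamma); b1 <- dsam:::tConst(tp, beta)
    fused <- dsam:::tBnReluDrop(tp, a, g1, b1, "k", bn1, dropP = 0)
    ref <- dsam:::tRelu(tp, dsam:::tBatchNormCols(tp, a, g1, b1, "k", bn2))
    expect_equal(dsam:::tVal(tp, fused), dsam:::tVal(tp, ref), tolerance = 1e-12)
    expect_equal(bn1$k, bn2$k, tolerance = 1e-12)
  }
})

test_that("fused attention level matches its composed-oracle gradient", {
  set.seed(4)
  N <- 5L; Tlen <- 12L
  cfg <- dsamConfig(nRois = N, tPoints = Tlen, temporalHeads = 2L,
                    temporalEmbed = 8L, spatialHeads = 3L, dropout = 0)
  params <- initDsamParams(cfg, 2)
  x <- testMatrix(N, Tlen)
  xcol <- matrix(as.vector(t(x)), ncol = 1L)
  lossOf <- function(p) {
    tp <- dsam:::tapeNew(training = FALSE)
    pget <- function(nm) dsam:::tParam(tp, nm, p[[nm]])
    r <- dsam:::.tTattLevel(tp, dsam:::tConst(tp, xcol), pget, cfg, 1L, N, Tlen)
    dsam:::tVal(tp, dsam:::tSum(tp, dsam:::tMul(tp, r$y, r$y)))
  }
  tp <- dsam:::tapeNew(training = FALSE)
  pget <- function(nm) dsam:::tParam(tp, nm, params[[nm]])
  r <- dsam:::.tTattLevel(tp, dsam:::tConst(tp, xcol), pget, cfg, 1L, N, Tlen)
  root <- dsam:::tSum(tp, dsam:::tMul(tp, r$y, r$y))
  g <- dsam:::tapeParamGrads(tp, dsam:::tapeBackward(tp, root))
  h <- 1e-6
  set.seed(8)
  for (nm in c("tatt.WQ", "tatt.WK", "tatt.WV", "tatt.g", "tatt.be")) {
    k <- sample(length(params[[nm]]), 1L)
    pp <- params; pp[[nm]][k] <- pp[[nm]][k] + h
    pm <- params; pm[[nm]][k] <- pm[[nm]][k] - h
    fd <- (lossOf(pp) - lossOf(pm)) / (2 * h)
    # absolute floor guards against FD round-off on near-zero entries
    expect_lt(abs(g[[nm]][k] - fd), 1e-6 + 1e-3 * abs(fd),
              label = sprintf("analytic-vs-FD gap for %s", nm))
  }
})

test_that("gradients flow end to end and match finite differences", {
  co <- tinyCohort()
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  x <- batchData(co$batch)
  r <- endToEndGrads(params, cfg, x, co$labels, 1:4)
  h <- 1e-6
  set.seed(12)
  for (nm in c("tcn.b1.c1.W", "tatt.WK", "satt.h1.Wq", "rgin.l1.th1",
               "rgin.l2.bas.u2", "pool.l1.w", "head.W2")) {
    k <- sample(length(params[[nm]]), 1L)
    pp <- params; pp[[nm]][k] <- pp[[nm]][k] + h
    pm <- params; pm[[nm]][k] <- pm[[nm]][k] - h
    fd <- (endToEndLoss(pp, cfg, x, co$labels, 1:4) -
             endToEndLoss(pm, cfg, x, co$labels, 1:4)) / (2 * h)
    expect_equal(r$grads[[nm]][k], fd, tolerance = 1e-4,
                 label = paste("end-to-end grad", nm))
  }
})
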