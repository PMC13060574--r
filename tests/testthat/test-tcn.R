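test_that("dilated causal convolution matches the direct summation", {
  # hand example: x = [1,2,3,4], f = [1,1], d = 2 -> [1, 2, 4, 6]
  expect_equal(as.numeric(dilatedCausalConv(c(1, 2, 3, 4), c(1, 1), d = 2)),
               c(1, 2, 4, 6))
  expect_equal(dilatedCausalConv(matrix(0, 2, 6),
                                 array(rnorm(7 * 2 * 3), c(7, 2, 3)), d = 2),
               matrix(0, 3, 6))
  set.seed(21)
  for (case in list(list(cin = 1, cout = 1, K = 3, d = 1),
                    list(cin = 2, cout = 3, K = 5, d = 2),
                    list(cin = 3, cout = 2, K = 7, d = 4))) {
    x <- matrix(rnorm(case$cin * 20), case$cin, 20)
    W <- array(rnorm(case$K * case$cin * case$cout),
               c(case$K, case$cin, case$cout))
    bias <- rnorm(case$cout)
    expect_lt(max(abs(dilatedCausalConv(x, W, case$d, bias) -
                        oracleDilConv(x, W, case$d, bias))), 1e-6)
  }
  expect_error(dilatedCausalConv(c(1, 2), c(1, 1), d = 0), "positive")
})

test_that("d = 1 reduces to a regular causal convolution", {
  set.seed(22)
  x <- rnorm(16)
  f <- rnorm(4)
  y <- as.numeric(dilatedCausalConv(x, f, d = 1))
  # regular convolution with left zero padding, written directly
  ref <- vapply(seq_along(x), function(t) {
    ks <- seq_len(min(4, t))
    sum(f[ks] * x[t - ks + 1])
  }, 0)
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("a block is deterministic in eval mode and strictly causal", {
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  x <- testMatrix(1, 16) # block 1 consumes the single-channel raw series
  y1 <- runTcnBlock(x, params, 1, cfg)
  y2 <- runTcnBlock(x, params, 1, cfg)
  expect_identical(y1, y2)
  expect_equal(nrow(y1), cfg$channels[1])
  expect_equal(ncol(y1), 16L)
  # perturbing time t changes the block output only at times >= t
  for (t0 in c(1L, 5L, 16L)) {
    xp <- x
    xp[1, t0] <- xp[1, t0] + 1
    yp <- runTcnBlock(xp, params, 1, cfg)
    if (t0 > 1L) expect_lt(max(abs(yp[, 1:(t0 - 1), drop = FALSE] -
                                     y1[, 1:(t0 - 1), drop = FALSE])), 1e-10)
    expect_gt(max(abs(yp[, t0:16] - y1[, t0:16])), 0)
  }
  expect_error(runTcnBlock(testMatrix(3, 16), params, 2, cfg), "channel mismatch")
})

test_that("block channel counts follow the 8/16/32 configuration", {
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  x <- testMatrix(1, 20)
  b1 <- runTcnBlock(x, params, 1, cfg)
  b2 <- runTcnBlock(b1, params, 2, cfg)
  b3 <- runTcnBlock(b2, params, 3, cfg)
  expect_equal(c(nrow(b1), nrow(b2), nrow(b3)), c(8L, 16L, 32L))
})

test_that("multi-level encoding preserves shape, causality and ROI symmetry", {
  cfg <- tinyConfig()
  params <- tinyParams(cfg)
  N <- cfg$nRois; Tlen <- cfg$tPoints
  x <- testMatrix(N, Tlen)
  levels <- encodeMultilevel(x, params, cfg)
  expect_length(levels, 3L)
  for (lv in levels) expect_equal(dim(lv), c(N, Tlen))
  # final-time perturbation leaves all earlier outputs unchanged at every level
  xp <- x
  xp[, Tlen] <- xp[, Tlen] + 1
  levp <- encodeMultilevel(xp, params, cfg)
  for (l in 1:3)
    expect_lt(max(abs(levp[[l]][, 1:(Tlen - 1)] - levels[[l]][, 1:(Tlen - 1)])), 1e-9)
  # per-ROI weight sharing: permuting ROIs permutes outputs identically
  # (per-channel batch statistics are permutation-invariant)
  perm <- c(4L, 1L, 3L, 2L, 5L, 9L, 10L, 6L, 7L, 8L)
  levperm <- encodeMultilevel(x[perm, ], params, cfg)
  for (l in 1:3)
    expect_lt(max(abs(levperm[[l]] - levels[[l]][perm, ])), 1e-9)
})

test_that("the cumulative receptive field at level 3 spans 85 samples", {
  cfg <- dsamConfig(nRois = 2, tPoints = 120, dropout = 0)
  params <- initDsamParams(cfg, 4)
  # make rectifiers and normalisation transparent to the perturbation probe:
  # positive-shifted gains keep units active
  for (nm in names(params)) {
    if (grepl("\\.be$", nm)) params[[nm]] <- params[[nm]] + 1
  }
  x <- testMatrix(2, 120, seed = 9)
  base <- encodeMultilevel(x, params, cfg)[[3]]
  t0 <- 20L
  xp <- x
  xp[, t0] <- xp[, t0] + 0.5
  pert <- encodeMultilevel(xp, params, cfg)[[3]]
  changed <- which(colSums(abs(pert - base)) > 1e-9)
  # receptive field: 1 + sum_l 2*(K-1)*d_l = 1 + 2*6*(1+2+4) = 85
  expect_equal(min(changed), t0)
  expect_equal(max(changed), min(t0 + 85L - 1L, 120L))
})
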