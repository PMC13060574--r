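# Parameter initialisation and the full end-to-end forward pass.

.glorot <- function(fin, fout) {
  matrix(rnorm(fin * fout, 0, sqrt(2 / (fin + fout))), fin, fout)
}

#' Initialise a full parameter set
#'
#' Creates every learnable array of the model for a given configuration:
#' temporal convolution filters (He initialisation), the shared temporal
#' attention projections, per-head spatial key/query maps, per-layer cluster
#' assignments (positive uniform so the rectifier starts active), basis
#' matrices, layer MLPs, pooling projections (unit norm) and the head.
#'
#' @param cfg the `dsamConfig`.
#' @param seed integer seed (restores the caller's RNG state on exit).
#' @return Named list of parameter arrays.
#' @export
initDsamParams <- function(cfg, seed = cfg$seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  N <- cfg$nRois
  K <- cfg$kernelSize
  p <- list()
  cin <- 1L
  for (l in 1:3) {
    cout <- cfg$channels[l]
    for (j in 1:2) {
      pre <- sprintf("tcn.b%d.c%d", l, j)
      p[[paste0(pre, ".W")]] <- array(rnorm(K * cin * cout, 0, sqrt(2 / (cin * K))),
                                      c(K, cin, cout))
      p[[paste0(pre, ".b")]] <- numeric(cout)
      p[[paste0(pre, ".g")]] <- rep(1, cout)
      p[[paste0(pre, ".be")]] <- numeric(cout)
      cin <- cout
    }
    p[[sprintf("tcn.b%d.col.W", l)]] <- .glorot(cout, 1L)
    p[[sprintf("tcn.b%d.col.b", l)]] <- 0
  }
  E <- cfg$temporalEmbed
  p[["tatt.WQ"]] <- .glorot(N, E)
  p[["tatt.WK"]] <- .glorot(N, E)
  p[["tatt.WV"]] <- .glorot(N, N)
  p[["tatt.g"]] <- rep(1, N)
  p[["tatt.be"]] <- numeric(N)
  mSel <- floor(cfg$tPoints * cfg$topkThreshold)
  wSlice <- (3L * mSel) %/% cfg$spatialHeads
  if ((3L * mSel) %% cfg$spatialHeads != 0L)
    stop("selected feature width ", 3L * mSel,
         " is not divisible by spatialHeads = ", cfg$spatialHeads)
  for (h in seq_len(cfg$spatialHeads)) {
    p[[sprintf("satt.h%d.Wk", h)]] <- .glorot(wSlice, cfg$spatialEmbed)
    p[[sprintf("satt.h%d.Wq", h)]] <- .glorot(wSlice, cfg$spatialEmbed)
  }
  dins <- c(N, cfg$rginDims[1L])
  for (l in 1:2) {
    pre <- sprintf("rgin.l%d", l)
    din <- dins[l]; dout <- cfg$rginDims[l]
    p[[paste0(pre, ".th1")]] <- matrix(runif(N * cfg$nClusters, 0.5, 1.5) / cfg$nClusters,
                                       N, cfg$nClusters)
    for (u in seq_len(cfg$nClusters)) {
      p[[sprintf("%s.bas.u%d", pre, u)]] <- .glorot(dout, din)
    }
    p[[paste0(pre, ".bm")]] <- matrix(0, dout, din)
    p[[paste0(pre, ".eps")]] <- 0
    p[[paste0(pre, ".W1")]] <- .glorot(dout, dout)
    p[[paste0(pre, ".b1")]] <- numeric(dout)
    p[[paste0(pre, ".W2")]] <- .glorot(dout, dout)
    p[[paste0(pre, ".b2")]] <- numeric(dout)
    w <- rnorm(dout)
    p[[sprintf("pool.l%d.w", l)]] <- w / sqrt(sum(w^2))
  }
  emb <- 2L * sum(cfg$rginDims)
  p[["head.W1"]] <- .glorot(emb, cfg$mlpDims[1L])
  p[["head.b1"]] <- numeric(cfg$mlpDims[1L])
  p[["head.W2"]] <- .glorot(cfg$mlpDims[1L], cfg$mlpDims[2L])
  p[["head.b2"]] <- numeric(cfg$mlpDims[2L])
  p[["head.W3"]] <- .glorot(cfg$mlpDims[2L], 2L)
  p[["head.b3"]] <- numeric(2L)
  p
}

# Full forward pass for a minibatch of subjects on one tape.
#
# xArr: [S, N, T] standardized array; idx: subject indices of the batch;
# constGraphs: per-subject precomputed constant-mode edge lists (or NULL).
# Returns node ids for the logits and the per-subject/per-layer pooling
# scores, plus detached per-subject learned-connectivity values.
.dsamForwardBatch <- function(tp, params, bnState, cfg, xArr, idx,
                              constGraphs = NULL) {
  N <- cfg$nRois; Tlen <- cfg$tPoints
  B <- length(idx)
  x0 <- matrix(as.vector(aperm(xArr[idx, , , drop = FALSE], c(3L, 2L, 1L))),
               ncol = 1L)
  pget <- function(nm) tParam(tp, nm, params[[nm]])
  stack <- .tTcnStack(tp, tConst(tp, x0), pget, cfg, Tlen, bnState)
  mSel <- floor(Tlen * cfg$topkThreshold)
  if (mSel < 1L) stop("topkThreshold keeps zero time points")
  att <- lapply(stack$levels, function(lv) {
    .tTattLevel(tp, lv, pget, cfg, B, N, Tlen)
  })
  logitRows <- vector("list", B)
  poolScores <- list(vector("list", B), vector("list", B))
  attfc <- vector("list", B)
  keptT <- replicate(B, vector("list", 3L), simplify = FALSE)
  for (b in seq_len(B)) {
    off <- (b - 1L) * N * Tlen
    selCols <- vector("list", 3L)
    for (l in 1:3) {
      lev <- tSubjectMat(tp, att[[l]]$y, off, N, Tlen)
      sc <- if (cfg$scoreMode == "attention") colSums(att[[l]]$A[, , b])
            else colMeans(abs(tVal(tp, lev)))
      keepT <- sort(.topIdx(sc, mSel))
      keptT[[b]][[l]] <- keepT
      selCols[[l]] <- tCols(tp, lev, keepT)
    }
    that <- tCbind(tp, selCols)
    lc <- .tLearnConnectivity(tp, that, pget, cfg)
    H <- lc$att
    attfc[[b]] <- tVal(tp, H)
    if (cfg$edgeMode == "dynamic") {
      R <- .tPearsonRows(tp, that)
      e <- .selectEdges(tVal(tp, R), cfg$edgeKeepFraction, cfg$rankEdgesBy)
      ew <- tGather2(tp, R, e$i, e$j)
      Aw <- tScatterSym(tp, ew, e$i, e$j, N)
    } else {
      g <- constGraphs[[idx[b]]]
      A <- matrix(0, N, N)
      A[cbind(g$i, g$j)] <- g$r
      A[cbind(g$j, g$i)] <- g$r
      Aw <- tConst(tp, A)
    }
    keptOrig <- seq_len(N)
    pooled <- vector("list", 2L)
    for (l in 1:2) {
      Hc <- .tRginLayer(tp, H, Aw, pget, l, keptOrig, cfg$nClusters)
      pl <- .tTopkPool(tp, Hc, Aw, sprintf("pool.l%d.w", l), pget,
                       cfg$poolingRatio)
      poolScores[[l]][[b]] <- list(st = pl$st, stVal = pl$stVal, kept = pl$keep)
      keptOrig <- keptOrig[pl$keep]
      H <- pl$H
      Aw <- pl$Aw
      pooled[[l]] <- H
    }
    ro <- tCbind(tp, unlist(lapply(pooled, function(Hp) {
      list(tColMeansRow(tp, Hp), tColMaxRow(tp, Hp))
    }), use.names = FALSE))
    h1 <- tRelu(tp, tAddBias(tp, tMatmul(tp, ro, pget("head.W1")), pget("head.b1")))
    h2 <- tRelu(tp, tAddBias(tp, tMatmul(tp, h1, pget("head.W2")), pget("head.b2")))
    logitRows[[b]] <- tAddBias(tp, tMatmul(tp, h2, pget("head.W3")), pget("head.b3"))
  }
  list(logits = tRbind(tp, unlist(logitRows)), poolScores = poolScores,
       attFC = attfc, keptTimepoints = keptT)
}

# Pearson correlation of feature rows, differentiably.
.tPearsonRows <- function(tp, x) {
  xc <- tRowCenter(tp, x)
  d <- tRowL2(tp, xc)
  tDivOuter(tp, tMatmulT(tp, xc, xc), d)
}

# Composite loss on the tape. Returns node ids plus a numeric breakdown.
.tTotalLoss <- function(tp, fwd, labels, cfg, pget) {
  ce <- tSoftmaxCE(tp, fwd$logits, labels)
  total <- ce
  unitVals <- numeric(2L)
  tpkVals <- numeric(2L)
  for (l in 1:2) {
    u <- tSqDev1(tp, tVnorm(tp, pget(sprintf("pool.l%d.w", l))))
    unitVals[l] <- tVal(tp, u)
    total <- tAdd(tp, total, u)
    B <- length(fwd$poolScores[[l]])
    acc <- NULL
    for (b in seq_len(B)) {
      ps <- fwd$poolScores[[l]][[b]]
      target <- as.numeric(seq_along(ps$stVal) %in% ps$kept)
      bl <- tBCELogits(tp, ps$st, target)
      acc <- if (is.null(acc)) bl else tAdd(tp, acc, bl)
    }
    tpkL <- tScale(tp, acc, 1 / B)
    tpkVals[l] <- tVal(tp, tpkL)
    total <- tAdd(tp, total, tScale(tp, tpkL, cfg$lambdaTopk))
  }
  list(total = total, ce = tVal(tp, ce), unit = unitVals, tpk = tpkVals)
}

# Precompute constant-mode edge lists for every subject.
.constantGraphs <- function(xArr, cfg) {
  lapply(seq_len(dim(xArr)[1L]), function(s) {
    R <- pearsonMatrix(xArr[s, , ])
    .selectEdges(R, cfg$edgeKeepFraction, cfg$rankEdgesBy)
  })
}

#' Forward pass of a fitted model
#'
#' Runs the full architecture in eval mode (running batch-normalisation
#' moments, inert dropout) and returns class-1 probabilities.
#'
#' @param fit a [DsamFit-class].
#' @param batch an [RoiTimeSeriesBatch-class] (standardized).
#' @param batchSize subjects per forward chunk.
#' @return Numeric vector of class-1 probabilities, one per subject.
#' @export
predictDsam <- function(fit, batch, batchSize = 32L) {
  cfg <- fit@config
  xArr <- batchData(batch)
  S <- dim(xArr)[1L]
  cg <- if (cfg$edgeMode == "constant") .constantGraphs(xArr, cfg) else NULL
  probs <- numeric(S)
  bn <- as.environment(fit@bnStats)
  for (chunk in split(seq_len(S), ceiling(seq_len(S) / batchSize))) {
    tp <- tapeNew(training = FALSE)
    fwd <- .dsamForwardBatch(tp, fit@params, bn, cfg, xArr, chunk, cg)
    probs[chunk] <- softmaxRows(tVal(tp, fwd$logits))[, 2L]
  }
  probs
}

#' Selected time points of every subject
#'
#' Eval-mode forward pass returning, per subject and temporal level, the
#' kept time-point indices (ascending, 1-based); exportable as a JSON mask
#' for interpretability.
#'
#' @param fit a [DsamFit-class].
#' @param batch an [RoiTimeSeriesBatch-class].
#' @param jsonPath optional path; when given, the masks are written as JSON
#'   keyed by subject id and level.
#' @return A list over subjects of lists over levels of index vectors.
#' @export
selectedTimepoints <- function(fit, batch, jsonPath = NULL) {
  cfg <- fit@config
  xArr <- batchData(batch)
  S <- dim(xArr)[1L]
  bn <- as.environment(fit@bnStats)
  cg <- if (cfg$edgeMode == "constant") .constantGraphs(xArr, cfg) else NULL
  out <- vector("list", S)
  for (chunk in split(seq_len(S), ceiling(seq_len(S) / 32L))) {
    tp <- tapeNew(training = FALSE)
    fwd <- .dsamForwardBatch(tp, fit@params, bn, cfg, xArr, chunk, cg)
    out[chunk] <- fwd$keptTimepoints
  }
  names(out) <- subjectIds(batch)
  out <- lapply(out, function(lv) {
    names(lv) <- sprintf("level%d", seq_along(lv))
    lv
  })
  if (!is.null(jsonPath))
    jsonlite::write_json(out, jsonPath, auto_unbox = FALSE)
  out
}

#' Cluster assignments of a fitted model
#'
#' The learned nonnegative ROI-to-cluster assignment matrix
#' `relu(theta1)` of a graph layer, optionally written as an ROI x cluster
#' TSV for interpretation.
#'
#' @param fit a [DsamFit-class].
#' @param layer graph layer index.
#' @param path optional TSV output path.
#' @return `[N, K_cl]` nonnegative matrix.
#' @export
clusterAssignments <- function(fit, layer = 1L, path = NULL) {
  a <- pmax(fit@params[[sprintf("rgin.l%d.th1", layer)]], 0)
  rownames(a) <- sprintf("roi%03d", seq_len(nrow(a)))
  colnames(a) <- sprintf("cluster%d", seq_len(ncol(a)))
  if (!is.null(path))
    write.table(data.frame(roi = rownames(a), a, check.names = FALSE), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  a
}

#' Extract the learned connectivity of every subject
#'
#' Eval-mode forward pass through the temporal and self-attention blocks,
#' returning each subject's directed connectivity matrix.
#'
#' @param fit a [DsamFit-class].
#' @param batch an [RoiTimeSeriesBatch-class].
#' @param batchSize subjects per forward chunk.
#' @return `[S, N, N]` array of row-stochastic matrices.
#' @export
extractConnectivity <- function(fit, batch, batchSize = 32L) {
  cfg <- fit@config
  xArr <- batchData(batch)
  S <- dim(xArr)[1L]
  N <- cfg$nRois
  out <- array(0, c(S, N, N))
  bn <- as.environment(fit@bnStats)
  cg <- if (cfg$edgeMode == "constant") .constantGraphs(xArr, cfg) else NULL
  for (chunk in split(seq_len(S), ceiling(seq_len(S) / batchSize))) {
    tp <- tapeNew(training = FALSE)
    fwd <- .dsamForwardBatch(tp, fit@params, bn, cfg, xArr, chunk, cg)
    for (b in seq_along(chunk)) out[chunk[b], , ] <- fwd$attFC[[b]]
  }
  out
}
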