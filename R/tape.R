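# Reverse-mode automatic differentiation on a linear tape.
#
# A tape holds node values in creation order; a node handle is an integer
# index. Each non-leaf node stores its parent indices and a backward closure
# mapping the node's output gradient to one gradient per parent (NULL = no
# gradient). tapeBackward() walks the tape once in reverse. Values are plain
# numeric scalars, vectors, matrices or arrays; gradients have the same shape
# as the value they correspond to.
#
# Constraint: index-selection ops (tRows/tCols/tGather2) assume the index
# vectors contain no duplicates; all call sites in this package satisfy that.

tapeNew <- function(training = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 1024L)
  tp$backs <- vector("list", 1024L)
  tp$n <- 0L
  tp$pmap <- new.env(parent = emptyenv()) # parameter name -> node id
  tp$training <- isTRUE(training)
  tp
}

.tpush <- function(tp, val, parents = NULL, vjp = NULL) {
  # force lazy arguments first: evaluating them may push further nodes, and
  # the index of this node must come after theirs
  force(val); force(parents); force(vjp)
  n <- tp$n + 1L
  if (n > length(tp$vals)) {
    length(tp$vals) <- 2L * n
    length(tp$backs) <- 2L * n
  }
  tp$vals[[n]] <- val
  if (!is.null(vjp)) tp$backs[[n]] <- list(p = as.integer(parents), f = vjp)
  tp$n <- n
  n
}

# force(id) first: evaluating a lazy argument may push new nodes and grow
# the value list, which must happen before the list is fetched.
tVal <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

tConst <- function(tp, v) .tpush(tp, v)

# Inject (or re-use) a named parameter leaf on this tape.
tParam <- function(tp, name, v) {
  id <- tp$pmap[[name]]
  if (!is.null(id)) return(id)
  id <- .tpush(tp, v)
  tp$pmap[[name]] <- id
  id
}

# Reverse pass from scalar node `root`; returns the list of gradients indexed
# by node id (only parameter leaves and `keep` ids are retained; intermediate
# gradients are dropped as soon as they have been consumed to bound memory).
tapeBackward <- function(tp, root, keep = integer(0)) {
  gr <- vector("list", tp$n)
  gr[[root]] <- 1
  keepMask <- logical(tp$n)
  keepMask[keep] <- TRUE
  for (nm in ls(tp$pmap)) keepMask[tp$pmap[[nm]]] <- TRUE
  for (i in rev(seq_len(tp$n))) {
    g <- gr[[i]]
    if (is.null(g)) next
    b <- tp$backs[[i]]
    if (is.null(b)) next
    pg <- b$f(g)
    p <- b$p
    for (k in seq_along(p)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      j <- p[k]
      gr[[j]] <- if (is.null(gr[[j]])) gk else gr[[j]] + gk
    }
    if (!keepMask[i]) gr[i] <- list(NULL)
  }
  gr
}

# Named list of parameter gradients (zero-filled for parameters the loss did
# not reach).
tapeParamGrads <- function(tp, gr) {
  out <- list()
  for (nm in ls(tp$pmap)) {
    id <- tp$pmap[[nm]]
    g <- gr[[id]]
    if (is.null(g)) {
      v <- tp$vals[[id]]
      g <- array(0, dim = if (is.null(dim(v))) length(v) else dim(v))
      if (is.null(dim(v))) g <- as.numeric(g)
    }
    out[[nm]] <- g
  }
  out
}

## ---- arithmetic -----------------------------------------------------------

tAdd <- function(tp, a, b) {
  .tpush(tp, tVal(tp, a) + tVal(tp, b), c(a, b), function(g) list(g, g))
}

tSub <- function(tp, a, b) {
  .tpush(tp, tVal(tp, a) - tVal(tp, b), c(a, b), function(g) list(g, -g))
}

tMul <- function(tp, a, b) {
  av <- tVal(tp, a); bv <- tVal(tp, b)
  .tpush(tp, av * bv, c(a, b), function(g) list(g * bv, g * av))
}

tScale <- function(tp, a, s) {
  .tpush(tp, tVal(tp, a) * s, a, function(g) list(g * s))
}

tAddConst <- function(tp, a, c0) {
  .tpush(tp, tVal(tp, a) + c0, a, function(g) list(g))
}

# Add a length-ncol bias vector to every row of a matrix.
tAddBias <- function(tp, a, b) {
  av <- tVal(tp, a); bv <- tVal(tp, b)
  n <- nrow(av)
  .tpush(tp, av + matrix(bv, n, length(bv), byrow = TRUE), c(a, b),
         function(g) list(g, colSums(g)))
}

# Multiply each row i of `a` by v[i] (v a length-nrow vector node).
tMulColVec <- function(tp, a, v) {
  av <- tVal(tp, a); vv <- as.numeric(tVal(tp, v))
  .tpush(tp, av * vv, c(a, v),
         function(g) list(g * vv, rowSums(g * av)))
}

# Multiply by a scalar-valued node.
tMulScalarNode <- function(tp, a, s) {
  av <- tVal(tp, a); sv <- as.numeric(tVal(tp, s))
  .tpush(tp, av * sv, c(a, s),
         function(g) list(g * sv, sum(g * av)))
}

# Divide by a scalar-valued node.
tDivScalarNode <- function(tp, a, s) {
  av <- tVal(tp, a); sv <- as.numeric(tVal(tp, s))
  .tpush(tp, av / sv, c(a, s),
         function(g) list(g / sv, -sum(g * av) / sv^2))
}

## ---- linear algebra -------------------------------------------------------

tMatmul <- function(tp, a, b) {
  av <- tVal(tp, a); bv <- tVal(tp, b)
  .tpush(tp, av %*% bv, c(a, b),
         function(g) list(g %*% t(bv), crossprod(av, g)))
}

# A %*% t(B) in one node.
tMatmulT <- function(tp, a, b) {
  av <- tVal(tp, a); bv <- tVal(tp, b)
  .tpush(tp, tcrossprod(av, bv), c(a, b),
         function(g) list(g %*% bv, crossprod(g, av)))
}

tTrans <- function(tp, a) {
  .tpush(tp, t(tVal(tp, a)), a, function(g) list(t(g)))
}

## ---- nonlinearities -------------------------------------------------------

tRelu <- function(tp, a) {
  av <- tVal(tp, a)
  y <- av * (av > 0)
  .tpush(tp, y, a, function(g) list(g * (av > 0)))
}

tSigmoid <- function(tp, a) {
  y <- 1 / (1 + exp(-tVal(tp, a)))
  .tpush(tp, y, a, function(g) list(g * y * (1 - y)))
}

# Row-wise softmax with a max shift for stability.
tSoftmaxRows <- function(tp, a) {
  av <- tVal(tp, a)
  y <- softmaxRows(av)
  .tpush(tp, y, a, function(g) list(y * (g - rowSums(g * y))))
}

softmaxRows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

## ---- selection / assembly -------------------------------------------------

tCols <- function(tp, a, idx) {
  av <- tVal(tp, a)
  .tpush(tp, av[, idx, drop = FALSE], a, function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[, idx] <- g
    list(ga)
  })
}

tRows <- function(tp, a, idx) {
  av <- tVal(tp, a)
  .tpush(tp, av[idx, , drop = FALSE], a, function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[idx, ] <- g
    list(ga)
  })
}

tCbind <- function(tp, ids) {
  vals <- lapply(ids, function(i) tVal(tp, i))
  w <- vapply(vals, ncol, 1L)
  ends <- cumsum(w)
  starts <- c(1L, head(ends, -1L) + 1L)
  .tpush(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

tRbind <- function(tp, ids) {
  vals <- lapply(ids, function(i) tVal(tp, i))
  h <- vapply(vals, nrow, 1L)
  ends <- cumsum(h)
  starts <- c(1L, head(ends, -1L) + 1L)
  .tpush(tp, do.call(rbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

# Elementwise mean over a list of same-shaped matrices.
tMeanList <- function(tp, ids) {
  vals <- lapply(ids, function(i) tVal(tp, i))
  H <- length(ids)
  .tpush(tp, Reduce(`+`, vals) / H, unlist(ids), function(g) {
    gh <- g / H
    rep(list(gh), H)
  })
}

# Gather entries M[i,j] into a vector; the (i,j) pairs must be distinct.
tGather2 <- function(tp, a, ii, jj) {
  av <- tVal(tp, a)
  idx <- cbind(ii, jj)
  .tpush(tp, av[idx], a, function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[idx] <- g
    list(ga)
  })
}

# Symmetric weighted adjacency from an edge-value vector node: A[i,j]=A[j,i]=e.
tScatterSym <- function(tp, e, ii, jj, n) {
  ev <- as.numeric(tVal(tp, e))
  A <- matrix(0, n, n)
  A[cbind(ii, jj)] <- ev
  A[cbind(jj, ii)] <- ev
  .tpush(tp, A, e, function(g) list(g[cbind(ii, jj)] + g[cbind(jj, ii)]))
}

# Extract one stacked series block as an N x T matrix. The stacked layout is a
# single-column matrix with row index ((b-1)*T + t), series-major, time
# fastest; `offset` is the 0-based row offset of the block of N*T rows.
tSubjectMat <- function(tp, x, offset, N, Tlen) {
  xv <- tVal(tp, x)
  rows <- (offset + 1L):(offset + N * Tlen)
  m <- matrix(xv[rows, 1L], N, Tlen, byrow = TRUE)
  .tpush(tp, m, x, function(g) {
    gx <- matrix(0, nrow(xv), 1L)
    gx[rows, 1L] <- as.vector(t(g))
    list(gx)
  })
}

## ---- reductions -----------------------------------------------------------

tSum <- function(tp, a) {
  av <- tVal(tp, a)
  .tpush(tp, sum(av), a, function(g) {
    list(array(g, dim = if (is.null(dim(av))) length(av) else dim(av)))
  })
}

tMeanAll <- function(tp, a) {
  av <- tVal(tp, a)
  n <- length(av)
  .tpush(tp, sum(av) / n, a, function(g) {
    gv <- array(g / n, dim = if (is.null(dim(av))) n else dim(av))
    list(gv)
  })
}

# Column means as a 1 x C row matrix (mean over rows = over graph nodes).
tColMeansRow <- function(tp, a) {
  av <- tVal(tp, a)
  n <- nrow(av)
  .tpush(tp, matrix(colMeans(av), 1L), a, function(g) {
    list(matrix(rep(g / n, each = n), n, ncol(av)))
  })
}

# Column-wise max as a 1 x C row matrix; subgradient routes to the argmax row.
tColMaxRow <- function(tp, a) {
  av <- tVal(tp, a)
  am <- max.col(t(av), ties.method = "first")
  y <- av[cbind(am, seq_len(ncol(av)))]
  .tpush(tp, matrix(y, 1L), a, function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[cbind(am, seq_len(ncol(av)))] <- as.numeric(g)
    list(ga)
  })
}

## ---- normalisation --------------------------------------------------------

# Center each row at its mean.
tRowCenter <- function(tp, a) {
  av <- tVal(tp, a)
  .tpush(tp, av - rowMeans(av), a, function(g) list(g - rowMeans(g)))
}

# Row L2 norms as a vector node (floored away from zero).
tRowL2 <- function(tp, a, eps = 1e-12) {
  av <- tVal(tp, a)
  d <- sqrt(pmax(rowSums(av * av), eps^2))
  .tpush(tp, d, a, function(g) list((g / d) * av))
}

# M / outer(d, d) with d a vector node.
tDivOuter <- function(tp, m, d) {
  mv <- tVal(tp, m); dv <- as.numeric(tVal(tp, d))
  o <- outer(dv, dv)
  y <- mv / o
  .tpush(tp, y, c(m, d), function(g) {
    gy <- g * y
    list(g / o, -(rowSums(gy) + colSums(gy)) / dv)
  })
}

# Vector L2 norm as a scalar node.
tVnorm <- function(tp, a, eps = 1e-12) {
  av <- as.numeric(tVal(tp, a))
  nv <- sqrt(max(sum(av * av), eps^2))
  .tpush(tp, nv, a, function(g) list(g * av / nv))
}

# (||w|| - 1)^2 on a scalar-norm node.
tSqDev1 <- function(tp, s) {
  sv <- as.numeric(tVal(tp, s))
  .tpush(tp, (sv - 1)^2, s, function(g) list(2 * (sv - 1) * g))
}

# Z-score a vector node with the population SD; an (all but) constant vector
# maps to zeros with zero gradient (degenerate-score rule for pooling).
tZnormVec <- function(tp, a, eps = 1e-12) {
  av <- as.numeric(tVal(tp, a))
  n <- length(av)
  mu <- mean(av)
  sd0 <- sqrt(mean((av - mu)^2))
  if (sd0 < eps) {
    return(.tpush(tp, matrix(0, n, 1L), a, function(g) list(matrix(0, n, 1L))))
  }
  y <- (av - mu) / sd0
  .tpush(tp, matrix(y, n, 1L), a, function(g) {
    gv <- as.numeric(g)
    gx <- (gv - mean(gv) - y * mean(gv * y)) / sd0
    list(matrix(gx, n, 1L))
  })
}

# LayerNorm over rows within each column (per-token over features), with
# learnable per-row gain/bias. y[i,j] = gamma[i]*xhat[i,j] + beta[i].
tLayerNormCols <- function(tp, a, gamma, beta, eps = 1e-5) {
  av <- tVal(tp, a)
  gv <- as.numeric(tVal(tp, gamma)); bv <- as.numeric(tVal(tp, beta))
  n <- nrow(av)
  mu <- colMeans(av)
  xc <- av - matrix(mu, n, ncol(av), byrow = TRUE)
  s <- sqrt(colMeans(xc * xc) + eps)
  xh <- xc / matrix(s, n, ncol(av), byrow = TRUE)
  y <- xh * gv + bv
  .tpush(tp, y, c(a, gamma, beta), function(g) {
    gxh <- g * gv
    cm1 <- colMeans(gxh)
    cm2 <- colMeans(gxh * xh)
    ga <- (gxh -
             matrix(cm1, n, ncol(av), byrow = TRUE) -
             xh * matrix(cm2, n, ncol(av), byrow = TRUE)) /
      matrix(s, n, ncol(av), byrow = TRUE)
    list(ga, rowSums(g * xh), rowSums(g))
  })
}

# Batch normalisation per column (channel); rows are the batch dimension.
# Training mode uses batch statistics and updates running moments stored in
# `bnState[[key]]`; eval mode uses the stored moments.
tBatchNormCols <- function(tp, a, gamma, beta, key, bnState,
                           momentum = 0.1, eps = 1e-5) {
  av <- tVal(tp, a)
  gv <- as.numeric(tVal(tp, gamma)); bv <- as.numeric(tVal(tp, beta))
  n <- nrow(av); C <- ncol(av)
  st <- bnState[[key]]
  if (is.null(st)) {
    st <- list(rm = numeric(C), rv = rep(1, C))
    bnState[[key]] <- st
  }
  if (tp$training) {
    mu <- colMeans(av)
    xc <- av - matrix(mu, n, C, byrow = TRUE)
    v <- colMeans(xc * xc)
    bnState[[key]] <- list(rm = (1 - momentum) * st$rm + momentum * mu,
                           rv = (1 - momentum) * st$rv + momentum * v)
    s <- sqrt(v + eps)
    xh <- xc / matrix(s, n, C, byrow = TRUE)
    y <- xh * matrix(gv, n, C, byrow = TRUE) + matrix(bv, n, C, byrow = TRUE)
    .tpush(tp, y, c(a, gamma, beta), function(g) {
      gxh <- g * matrix(gv, n, C, byrow = TRUE)
      cm1 <- colMeans(gxh)
      cm2 <- colMeans(gxh * xh)
      ga <- (gxh -
               matrix(cm1, n, C, byrow = TRUE) -
               xh * matrix(cm2, n, C, byrow = TRUE)) /
        matrix(s, n, C, byrow = TRUE)
      list(ga, colSums(g * xh), colSums(g))
    })
  } else {
    s <- sqrt(st$rv + eps)
    xh <- (av - matrix(st$rm, n, C, byrow = TRUE)) / matrix(s, n, C, byrow = TRUE)
    y <- xh * matrix(gv, n, C, byrow = TRUE) + matrix(bv, n, C, byrow = TRUE)
    .tpush(tp, y, c(a, gamma, beta), function(g) {
      list(g * matrix(gv / s, n, C, byrow = TRUE), colSums(g * xh), colSums(g))
    })
  }
}

# Fused batch norm -> rectifier -> inverted dropout over a stacked tensor
# (one C++ pass each way); semantically identical to tBatchNormCols + tRelu +
# tDropout. Updates the running moments in `bnState[[key]]` in training mode.
tBnReluDrop <- function(tp, x, gamma, beta, key, bnState, dropP,
                        momentum = 0.1, eps = 1e-5) {
  xv <- tVal(tp, x)
  gv <- as.numeric(tVal(tp, gamma)); bv <- as.numeric(tVal(tp, beta))
  st <- bnState[[key]] %||% list(rm = numeric(ncol(xv)), rv = rep(1, ncol(xv)))
  r <- dsam_bnrd_fwd(xv, gv, bv, st$rm, st$rv, momentum, eps, tp$training, dropP)
  if (tp$training) bnState[[key]] <- list(rm = as.numeric(r$rm), rv = as.numeric(r$rv))
  y <- r$y
  mu <- as.numeric(r$mu); s <- as.numeric(r$s)
  training <- tp$training
  .tpush(tp, y, c(x, gamma, beta), function(g) {
    b <- dsam_bnrd_bwd(xv, y, g, gv, mu, s, training, dropP)
    list(b$gx, as.numeric(b$ggamma), as.numeric(b$gbeta))
  })
}

## ---- stochastic -----------------------------------------------------------

# Inverted dropout; identity (no new node) when inert.
tDropout <- function(tp, a, p) {
  if (!tp$training || p <= 0) return(a)
  av <- tVal(tp, a)
  keep <- 1 - p
  mask <- (matrix(stats::runif(length(av)), nrow(av)) < keep) / keep
  .tpush(tp, av * mask, a, function(g) list(g * mask))
}

## ---- losses ---------------------------------------------------------------

# Mean softmax cross-entropy of logits (B x 2) against labels in {0,1}.
tSoftmaxCE <- function(tp, logits, labels) {
  lv <- tVal(tp, logits)
  P <- softmaxRows(lv)
  B <- nrow(lv)
  Y <- cbind(1 - labels, labels)
  ce <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
  .tpush(tp, ce, logits, function(g) list(g * (P - Y) / B))
}

# Mean binary cross-entropy of sigmoid(s) against a 0/1 target vector.
tBCELogits <- function(tp, s, target) {
  sv <- as.numeric(tVal(tp, s))
  p <- 1 / (1 + exp(-sv))
  n <- length(sv)
  loss <- -mean(target * log(pmax(p, 1e-12)) + (1 - target) * log(pmax(1 - p, 1e-12)))
  .tpush(tp, loss, s, function(g) list(matrix(g * (p - target) / n, n, 1L)))
}

## ---- convolution ----------------------------------------------------------

# Dilated causal convolution over stacked series. x is (B*T) x Cin with each
# series occupying T contiguous rows; W is a (K, Cin, Cout) array, b length
# Cout. Left zero padding of (K-1)*d is implicit.
tDilConv <- function(tp, x, W, b, d, Tlen) {
  xv <- tVal(tp, x); Wv <- tVal(tp, W); bv <- as.numeric(tVal(tp, b))
  dims <- dim(Wv)
  y <- dsam_conv_fwd(xv, as.numeric(Wv), dims[1L], dims[2L], dims[3L],
                     as.integer(Tlen), as.integer(d), bv)
  .tpush(tp, y, c(x, W, b), function(g) {
    r <- dsam_conv_bwd(xv, as.numeric(Wv), g, dims[1L], dims[2L], dims[3L],
                       as.integer(Tlen), as.integer(d))
    list(r$gx, array(r$gw, dims), as.numeric(r$gb))
  })
}
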