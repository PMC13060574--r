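# Independent oracles used across the suite. These deliberately re-derive
# every quantity with naive loops / closed forms, separate from the package's
# computation paths.

# Direct summation form of the dilated causal convolution:
# y[o, t] = bias[o] + sum_{c, s} W[s+1, c, o] * x[c, t - d*s] (zero outside).
oracleDilConv <- function(x, W, d, bias = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (is.null(dim(W))) W <- array(W, c(length(W), 1L, 1L))
  K <- dim(W)[1L]; Cin <- dim(W)[2L]; Cout <- dim(W)[3L]
  Tlen <- ncol(x)
  if (is.null(bias)) bias <- numeric(Cout)
  y <- matrix(0, Cout, Tlen)
  for (o in seq_len(Cout)) {
    for (t in seq_len(Tlen)) {
      acc <- bias[o]
      for (cc in seq_len(Cin)) {
        for (s in 0:(K - 1L)) {
          tt <- t - d * s
          if (tt >= 1L) acc <- acc + W[s + 1L, cc, o] * x[cc, tt]
        }
      }
      y[o, t] <- acc
    }
  }
  y
}

# Pencil-and-paper attention (tokens = time columns, single pass of the
# shared block) computed with explicit loops.
oracleAttend <- function(x, WQ, WK, WV, lnG, lnB, heads, eps = 1e-5) {
  Tlen <- ncol(x); N <- nrow(x)
  E <- ncol(WQ); dh <- E %/% heads
  Q <- t(x) %*% WQ
  K <- t(x) %*% WK
  V <- t(x) %*% WV
  A <- matrix(0, Tlen, Tlen)
  for (h in seq_len(heads)) {
    sl <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, sl, drop = FALSE] %*% t(K[, sl, drop = FALSE]) / sqrt(dh)
    for (i in seq_len(Tlen)) {
      e <- exp(S[i, ] - max(S[i, ]))
      A[i, ] <- A[i, ] + e / sum(e)
    }
  }
  A <- A / heads
  out <- t(A %*% V) + x
  y <- out
  for (tt in seq_len(Tlen)) {
    m <- mean(out[, tt])
    s <- sqrt(mean((out[, tt] - m)^2) + eps)
    y[, tt] <- lnG * (out[, tt] - m) / s + lnB
  }
  list(output = y, attention = A)
}

# Plain GIN-style update with a single shared weight matrix (the K_cl = 1,
# alpha = 1 special case), written independently with loops.
oracleGinConv <- function(H, A, W, b, eps, W1, b1, W2, b2) {
  n <- nrow(H)
  Z <- matrix(0, n, nrow(W))
  for (i in seq_len(n)) Z[i, ] <- (W + b) %*% H[i, ]
  agg <- matrix(0, n, nrow(W))
  for (i in seq_len(n)) {
    acc <- (1 + eps) * Z[i, ]
    for (j in seq_len(n)) if (A[i, j] != 0) acc <- acc + A[i, j] * Z[j, ]
    agg[i, ] <- acc
  }
  h1 <- pmax(agg %*% W1 + matrix(b1, n, length(b1), byrow = TRUE), 0)
  h1 %*% W2 + matrix(b2, n, length(b2), byrow = TRUE)
}

# Rank-statistic AUC by exhaustive pair counting.
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Tiny deterministic standardized input matrix.
testMatrix <- function(N, Tlen, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(N * Tlen), N, Tlen)
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2))
  (x - mu) / s
}
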