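# Correlation graph construction: Pearson correlation between node feature
# rows, global retention of the top fraction of undirected edges ranked by
# absolute correlation (signed r kept as the edge weight).

#' Pearson correlation between feature rows
#'
#' Symmetric correlation matrix with unit diagonal; rows with zero variance
#' yield correlation 0 against everything (flagged with a warning) rather
#' than NaN.
#'
#' @param features `[N, F]` matrix, F >= 2.
#' @return `[N, N]` correlation matrix.
#' @export
pearsonMatrix <- function(features) {
  if (ncol(features) < 2L) stop("correlation needs at least 2 feature columns")
  xc <- features - rowMeans(features)
  ss <- sqrt(rowSums(xc * xc))
  const <- ss < 1e-12
  if (any(const)) {
    warning(sum(const), " constant feature row(s); their correlations are set to 0")
    ss[const] <- 1
  }
  R <- tcrossprod(xc / ss)
  R[const, ] <- 0
  R[, const] <- 0
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- ifelse(const, 0, 1)
  R
}

# Rank candidate undirected edges and keep the top fraction.
# Ties break toward the lexicographically lower (i, j).
.selectEdges <- function(R, keepFraction, rankBy = "abs") {
  n <- nrow(R)
  iu <- which(upper.tri(R), arr.ind = TRUE)
  vals <- R[upper.tri(R)]
  m <- ceiling(keepFraction * length(vals))
  if (m < 1L) stop("edge retention keeps zero edges")
  metric <- if (rankBy == "abs") abs(vals) else vals
  keep <- order(-metric, iu[, 1L], iu[, 2L])[seq_len(m)]
  ord <- order(iu[keep, 1L], iu[keep, 2L])
  keep <- keep[ord]
  list(i = iu[keep, 1L], j = iu[keep, 2L], r = vals[keep])
}

#' Build the sparse undirected correlation graph
#'
#' Computes the Pearson correlation between node feature rows (the selected
#' temporal features in dynamic mode; the raw time series in constant mode),
#' keeps the top `ceiling(keepFraction * N(N-1)/2)` undirected edges ranked by
#' absolute correlation (ties toward the lower (i, j) pair), and attaches the
#' learned connectivity rows as node features. The signed correlation is the
#' edge weight.
#'
#' @param att a [LearnedConnectivity-class] (node features).
#' @param features `[N, F]` matrix the edges are computed from: the selected
#'   temporal features (dynamic mode) or the raw `[N, T]` series (constant
#'   mode).
#' @param keepFraction fraction of undirected edges kept, in (0, 1].
#' @param rankBy `"abs"` or `"signed"` edge ranking.
#' @return A [BrainGraph-class].
#' @export
buildGraph <- function(att, features, keepFraction = 0.30,
                       rankBy = c("abs", "signed")) {
  rankBy <- match.arg(rankBy)
  H <- nodeFeaturesFromConnectivity(att)
  if (nrow(H) != nrow(features))
    stop("node features and edge features disagree on N")
  R <- pearsonMatrix(features)
  e <- .selectEdges(R, keepFraction, rankBy)
  new("BrainGraph", nodeFeatures = H,
      edges = cbind(i = e$i, j = e$j), edgeWeights = e$r,
      nNodes = nrow(H))
}
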