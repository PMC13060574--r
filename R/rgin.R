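# ROI-aware relational graph isomorphism convolution, TopK node pooling,
# mean/max readout and the classification head.
#
# Per-node weight: W_i = sum_u alpha_iu * beta_u + b, where alpha =
# relu(theta1) rows are learned nonnegative cluster assignments (theta1 is
# indexed by ORIGINAL ROI id at every layer, so relabeling nodes together
# with their position encodings permutes everything consistently), beta_u are
# K_cl shared basis matrices and b a shared bias matrix. Node update (GIN
# convention, MLP over the full aggregate):
#   h_i' = MLP( (1 + eps) * W_i h_i + sum_j e_ij * W_j h_j ).

# Internal: one convolution layer. H: [Nl x din] node, Aw: [Nl x Nl] weighted
# adjacency node, keptOrig: original ROI ids of the current nodes.
.tRginLayer <- function(tp, H, Aw, pget, layer, keptOrig, nClusters) {
  pre <- sprintf("rgin.l%d", layer)
  alpha <- tRelu(tp, tRows(tp, pget(paste0(pre, ".th1")), keptOrig))
  Z <- tMatmulT(tp, H, pget(paste0(pre, ".bm")))
  for (u in seq_len(nClusters)) {
    Mu <- tMatmulT(tp, H, pget(sprintf("%s.bas.u%d", pre, u)))
    Z <- tAdd(tp, Z, tMulColVec(tp, Mu, tCols(tp, alpha, u)))
  }
  onePlusEps <- tAddConst(tp, pget(paste0(pre, ".eps")), 1)
  agg <- tAdd(tp, tMulScalarNode(tp, Z, onePlusEps), tMatmul(tp, Aw, Z))
  h1 <- tRelu(tp, tAddBias(tp, tMatmul(tp, agg, pget(paste0(pre, ".W1"))),
                           pget(paste0(pre, ".b1"))))
  tAddBias(tp, tMatmul(tp, h1, pget(paste0(pre, ".W2"))), pget(paste0(pre, ".b2")))
}

# Internal: TopK pooling. Returns pooled H, pooled Aw, kept positions, the
# normalized-score node and its value.
.tTopkPool <- function(tp, H, Aw, wName, pget, ratio) {
  Nl <- nrow(tVal(tp, H))
  w <- pget(wName)
  wcol <- .tpush(tp, matrix(tVal(tp, w), ncol = 1L), w,
                 function(g) list(as.numeric(g)))
  s <- tDivScalarNode(tp, tMatmul(tp, H, wcol), tVnorm(tp, w))
  st <- tZnormVec(tp, s)
  sv <- as.numeric(tVal(tp, st))
  m <- ceiling(ratio * Nl)
  keep <- sort(.topIdx(sv, m))
  Hp <- tRows(tp, tMulColVec(tp, H, tSigmoid(tp, st)), keep)
  Ap <- tRows(tp, tCols(tp, Aw, keep), keep)
  list(H = Hp, Aw = Ap, keep = keep, st = st, stVal = sv)
}

#' One relational graph-isomorphism convolution
#'
#' Updates every node by mixing the K_cl basis matrices with its learned
#' nonnegative cluster assignment, combining the epsilon-weighted self term
#' with the edge-weighted neighbour aggregation, and passing the result
#' through the layer's 2-layer MLP.
#'
#' @param graph a [BrainGraph-class] (or any list with `nodeFeatures` and a
#'   dense symmetric `adjacency`).
#' @param params named parameter list (uses the `rgin.l<layer>.*` entries).
#' @param layer layer index (selects the parameter set).
#' @param nClusters number of cluster basis matrices K_cl.
#' @param keptOrig original ROI ids of the current nodes (defaults to 1..N).
#' @return `[N, d_out]` updated node-feature matrix.
#' @export
rginConv <- function(graph, params, layer = 1L, nClusters = 7L,
                     keptOrig = NULL) {
  H <- if (is(graph, "BrainGraph")) graph@nodeFeatures else graph$nodeFeatures
  A <- if (is(graph, "BrainGraph")) adjacencyMatrix(graph) else graph$adjacency
  din <- ncol(H)
  if (ncol(params[[sprintf("rgin.l%d.bm", layer)]]) != din)
    stop("node feature width ", din, " does not match layer ", layer, " input size")
  keptOrig <- keptOrig %||% seq_len(nrow(H))
  tp <- tapeNew(training = FALSE)
  pget <- function(nm) tParam(tp, nm, params[[nm]])
  out <- .tRginLayer(tp, tConst(tp, H), tConst(tp, A), pget, layer, keptOrig,
                     nClusters)
  tVal(tp, out)
}

#' TopK node pooling
#'
#' Scores nodes by projecting their features onto a learnable direction
#' (normalised by its length, so rescaling the projection vector leaves the
#' scores unchanged), z-normalises the scores, keeps the `ceiling(k * N)`
#' top-scoring nodes (ties toward the lower index), gates the kept features
#' by the sigmoid of their normalised scores, and restricts the graph to the
#' induced subgraph. If all scores are equal the normalised scores are
#' defined as zero and the lowest-index nodes are kept.
#'
#' @param H `[N, d]` node features.
#' @param adjacency dense symmetric `[N, N]` weighted adjacency.
#' @param omega length-d projection vector.
#' @param ratio keep ratio k in (0, 1].
#' @return List: `H` (pooled gated features), `adjacency` (induced subgraph),
#'   `keep` (kept node positions, ascending), `scores` (normalised scores of
#'   all nodes).
#' @export
topkPool <- function(H, adjacency, omega, ratio = 0.5) {
  if (!(ratio > 0 && ratio <= 1)) stop("ratio must lie in (0, 1]")
  if (sqrt(sum(omega^2)) < 1e-12) stop("projection vector must be nonzero")
  params <- list(w = as.numeric(omega))
  tp <- tapeNew(training = FALSE)
  pget <- function(nm) tParam(tp, nm, params[[nm]])
  r <- .tTopkPool(tp, tConst(tp, H), tConst(tp, adjacency), "w", pget, ratio)
  list(H = tVal(tp, r$H), adjacency = tVal(tp, r$Aw), keep = r$keep,
       scores = r$stVal)
}

#' Mean/max graph readout
#'
#' Concatenates the elementwise mean and maximum over nodes for every pooled
#' layer, then concatenates the layers: the embedding length is
#' `sum_l 2 * d_l` (128 for the default two 32-unit layers).
#'
#' @param layerFeatures list of `[N_l, d_l]` node-feature matrices.
#' @return Numeric embedding vector.
#' @export
readoutGraph <- function(layerFeatures) {
  if (!length(layerFeatures)) stop("readout needs at least one layer")
  unlist(lapply(layerFeatures, function(H) {
    if (!nrow(H)) stop("readout of an empty graph")
    c(colMeans(H), apply(H, 2L, max))
  }), use.names = FALSE)
}

#' Classification head
#'
#' Fully connected head applied to the graph embedding in size order
#' (embedding -> mlpDims\[1\] -> mlpDims\[2\] -> 2) with rectifier
#' activations between the layers.
#'
#' @param embedding numeric embedding vector.
#' @param params named parameter list (uses the `head.*` entries).
#' @return Length-2 logit vector.
#' @export
classifyEmbedding <- function(embedding, params) {
  h <- matrix(embedding, 1L)
  h <- pmax(h %*% params[["head.W1"]] + rep(params[["head.b1"]], each = 1L), 0)
  h <- pmax(h %*% params[["head.W2"]] + rep(params[["head.b2"]], each = 1L), 0)
  as.numeric(h %*% params[["head.W3"]] + params[["head.b3"]])
}

## ---- parameterisation helpers ---------------------------------------------

#' Per-node weight matrix from the position-encoding parameterisation
#'
#' `W_i = theta2 %*% relu(theta1[i, ]) + b` reshaped to `[dOut, dIn]`, with
#' `theta2` the `[dOut*dIn, K]` basis-mixing map. Equivalent to
#' [rginWeightFromBases()] when the columns of `theta2` are the vectorised
#' basis matrices.
#'
#' @param theta1 `[N, K]` assignment parameters.
#' @param theta2 `[dOut*dIn, K]` mixing map.
#' @param b `[dOut, dIn]` bias matrix.
#' @param i node index.
#' @param dOut,dIn output/input dimensions.
#' @return `[dOut, dIn]` weight matrix.
#' @export
rginWeightFromTheta <- function(theta1, theta2, b, i, dOut, dIn) {
  alpha <- pmax(theta1[i, ], 0)
  matrix(theta2 %*% alpha, dOut, dIn) + b
}

#' @rdname rginWeightFromTheta
#' @param betas list of K `[dOut, dIn]` basis matrices.
#' @export
rginWeightFromBases <- function(theta1, betas, b, i) {
  alpha <- pmax(theta1[i, ], 0)
  Reduce(`+`, Map(function(a, B) a * B, alpha, betas)) + b
}

#' Learnable parameter count of one convolution layer
#'
#' `K_cl * dOut * dIn` basis values plus `N * K_cl` assignments plus the
#' `dOut * dIn` bias: strictly fewer than N full per-node matrices for the
#' default sizes.
#'
#' @param n number of nodes.
#' @param k number of clusters.
#' @param dIn,dOut layer dimensions.
#' @return Integer parameter count (excluding the layer MLP and epsilon).
#' @export
rginParamCount <- function(n, k, dIn, dOut) {
  k * dOut * dIn + n * k + dOut * dIn
}
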