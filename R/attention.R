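# Temporal attention with top-K time-point selection, and the node-node
# self-attention block that produces the learned directed connectivity.
#
# Temporal block: tokens are time points, each carrying the N-dim column of
# the level matrix. One shared parameter set serves all three levels. The
# per-head T x T attention matrices are averaged into a single matrix that
# both produces the attended output (through the value projection, residual
# and per-token layer normalisation) and is column-summed to score time
# points: the score of time point t is the total attention it receives.

# Internal: one shared-attention level over the whole stacked batch, as a
# single fused node. xcol is the stacked (B*N*T) x 1 level output; returns
# the node of the normalised stacked output plus the detached [T, T, B]
# attention cube (used for scoring and interpretability export).
.tTattLevel <- function(tp, xcol, pget, cfg, B, N, Tlen) {
  wq <- pget("tatt.WQ"); wk <- pget("tatt.WK"); wv <- pget("tatt.WV")
  lg <- pget("tatt.g"); lb <- pget("tatt.be")
  H <- cfg$temporalHeads
  scale <- 1 / sqrt(cfg$temporalEmbed %/% H)
  xv <- tVal(tp, xcol)
  wqv <- tVal(tp, wq); wkv <- tVal(tp, wk); wvv <- tVal(tp, wv)
  lgv <- as.numeric(tVal(tp, lg)); lbv <- as.numeric(tVal(tp, lb))
  r <- dsam_tatt_fwd(xv, wqv, wkv, wvv, lgv, lbv, as.integer(B),
                     as.integer(N), as.integer(Tlen), as.integer(H), scale,
                     1e-5)
  id <- .tpush(tp, r$y, c(xcol, wq, wk, wv, lg, lb), function(g) {
    b <- dsam_tatt_bwd(g, xv, wqv, wkv, wvv, lgv, r$Q, r$K, r$A, r$res,
                       as.integer(B), as.integer(N), as.integer(Tlen),
                       as.integer(H), scale, 1e-5)
    list(b$gx, b$gWQ, b$gWK, b$gWV, as.numeric(b$glnG), as.numeric(b$glnB))
  })
  list(y = id, A = r$A)
}

#' Apply the shared temporal attention to one feature level
#'
#' @param x `[N, T]` level matrix.
#' @param params named parameter list (uses the `tatt.*` entries).
#' @param cfg the `dsamConfig`.
#' @return List with `output` (`[N, T]`, after the residual addition and
#'   per-token layer normalisation) and `attention` (the head-averaged
#'   row-stochastic `[T, T]` matrix).
#' @export
attendLevel <- function(x, params, cfg) {
  if (ncol(x) == 0L) stop("attention needs at least one time point")
  tp <- tapeNew(training = FALSE)
  pget <- function(nm) tParam(tp, nm, params[[nm]])
  xcol <- tConst(tp, matrix(as.vector(t(x)), ncol = 1L))
  r <- .tTattLevel(tp, xcol, pget, cfg, 1L, nrow(x), ncol(x))
  list(output = matrix(tVal(tp, r$y)[, 1L], nrow(x), ncol(x), byrow = TRUE),
       attention = r$A[, , 1L])
}

#' Score time points from an attention matrix
#'
#' The score of time point t is its column sum in the row-stochastic
#' attention matrix: the total attention received. Scores are nonnegative and
#' sum to T.
#'
#' @param attention row-stochastic `[T, T]` matrix.
#' @return Numeric score vector of length T.
#' @export
scoreTimepoints <- function(attention) {
  colSums(attention)
}

# Descending top-m indices with ties broken toward the lower index.
.topIdx <- function(scores, m) {
  order(-scores, seq_along(scores))[seq_len(m)]
}

#' Keep the top-scoring time points of a level
#'
#' Retains the `floor(T * th)` highest-scoring time indices (ties broken
#' toward the earlier time point), restores them to ascending temporal order,
#' and applies the same selection to every ROI row.
#'
#' @param levelOut `[N, T]` attended level output.
#' @param scores length-T score vector.
#' @param th selection threshold in (0, 1].
#' @return List with `indices` (ascending, 1-based) and `features`
#'   (`[N, floor(T*th)]`).
#' @export
topkSelect <- function(levelOut, scores, th) {
  Tlen <- ncol(levelOut)
  if (!(th > 0 && th <= 1)) stop("th must lie in (0, 1]")
  m <- floor(Tlen * th)
  if (m < 1L) stop("floor(T * th) = 0: nothing would be kept")
  idx <- sort(.topIdx(scores, m))
  list(indices = idx, features = levelOut[, idx, drop = FALSE])
}

#' Attend, score and select across all three levels
#'
#' Runs the shared temporal attention independently on each level (one weight
#' set, level-specific scores), keeps the top `floor(T*th)` time points per
#' level, and concatenates the selections in level order 1, 2, 3.
#'
#' @param levels list of three `[N, T]` level matrices.
#' @param params named parameter list.
#' @param cfg the `dsamConfig`.
#' @return List with `features` (`[N, 3*floor(T*th)]`), `indices` (per-level
#'   kept time indices), `attention` (per-level `[T, T]` matrices).
#' @export
selectAndConcat <- function(levels, params, cfg) {
  if (length(levels) != 3L) stop("three levels expected")
  sel <- lapply(levels, function(lv) {
    r <- attendLevel(lv, params, cfg)
    sc <- if (cfg$scoreMode == "attention") scoreTimepoints(r$attention)
          else colMeans(abs(r$output))
    c(topkSelect(r$output, sc, cfg$topkThreshold), list(attention = r$attention))
  })
  list(features = do.call(cbind, lapply(sel, `[[`, "features")),
       indices = lapply(sel, `[[`, "indices"),
       attention = lapply(sel, `[[`, "attention"))
}

## ---- spatial self-attention ----------------------------------------------

# Internal: learned connectivity from the selected features node ([N x F]).
# The feature columns are divided into H contiguous per-level slices first;
# key/query projections act within each slice (Eq-style local heads); the
# softmax-normalised N x N head matrices are averaged.
.tLearnConnectivity <- function(tp, that, pget, cfg) {
  Fw <- ncol(tVal(tp, that))
  H <- cfg$spatialHeads
  if (Fw %% H != 0L)
    stop("feature width ", Fw, " is not divisible into ", H, " head slices")
  w <- Fw %/% H
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    sl <- ((h - 1L) * w + 1L):(h * w)
    Sl <- tCols(tp, that, sl)
    k <- tMatmul(tp, Sl, pget(sprintf("satt.h%d.Wk", h)))
    q <- tMatmul(tp, Sl, pget(sprintf("satt.h%d.Wq", h)))
    heads[[h]] <- tSoftmaxRows(tp, tScale(tp, tMatmulT(tp, q, k),
                                          1 / sqrt(cfg$spatialEmbed)))
  }
  list(att = if (H > 1L) tMeanList(tp, heads) else heads[[1L]], heads = heads)
}

#' Learn the directed connectivity matrix
#'
#' Node-node self-attention over the selected temporal features: the feature
#' vector of each ROI is split into contiguous per-head slices (one per
#' temporal level in the default configuration), each head embeds its slice
#' into keys and queries, forms a softmax-normalised N x N attention matrix,
#' and the heads are averaged. Every row of the result sums to 1; the matrix
#' is generally asymmetric and is read as directed connectivity.
#'
#' @param features `[N, F]` selected feature matrix (F divisible by the head
#'   count).
#' @param params named parameter list (uses the `satt.*` entries).
#' @param cfg the `dsamConfig`.
#' @return A [LearnedConnectivity-class].
#' @export
learnConnectivity <- function(features, params, cfg) {
  tp <- tapeNew(training = FALSE)
  pget <- function(nm) tParam(tp, nm, params[[nm]])
  r <- .tLearnConnectivity(tp, tConst(tp, features), pget, cfg)
  new("LearnedConnectivity", attFC = tVal(tp, r$att),
      perHead = lapply(r$heads, function(id) tVal(tp, id)))
}

#' Node features from learned connectivity
#'
#' Node i's feature vector is row i of the learned connectivity matrix: its
#' directed connectivity strengths to all nodes.
#'
#' @param att a [LearnedConnectivity-class].
#' @return `[N, N]` node-feature matrix.
#' @export
nodeFeaturesFromConnectivity <- function(att) {
  attFC(att)
}
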