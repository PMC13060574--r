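# S4 containers for the data objects that travel between stages.

#' ROI time-series batch
#'
#' Subjects x ROIs x time array of BOLD time series, one row of the per-subject
#' matrix per ROI. After [standardizeBatch()] every (subject, ROI) row has zero
#' mean and unit standard deviation; rows that were constant are mapped to all
#' zeros and recorded in `constantRows`.
#'
#' @slot data numeric array `[S, N, T]`.
#' @slot subjectIds character vector of length S.
#' @slot trSeconds repetition time in seconds, or `NA_real_` when unknown.
#' @slot standardized logical flag set by [standardizeBatch()].
#' @slot constantRows two-column integer matrix (subject, roi) of flagged rows.
#' @exportClass RoiTimeSeriesBatch
setClass("RoiTimeSeriesBatch",
  representation(data = "array", subjectIds = "character",
                 trSeconds = "numeric", standardized = "logical",
                 constantRows = "matrix"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-d array [S, N, T]")
    if (length(object@subjectIds) != d[1L])
      return("subjectIds length must equal the number of subjects")
    if (anyDuplicated(object@subjectIds)) return("subjectIds must be unique")
    TRUE
  })

#' Construct an [RoiTimeSeriesBatch-class] from an array or matrix
#'
#' @param data `[S, N, T]` array, or a single `[N, T]` matrix (S = 1).
#' @param subjectIds optional subject identifiers.
#' @param trSeconds optional repetition time (seconds).
#' @return An [RoiTimeSeriesBatch-class].
#' @export
roiTimeSeriesBatch <- function(data, subjectIds = NULL, trSeconds = NA_real_) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (is.null(subjectIds))
    subjectIds <- sprintf("sub-%03d", seq_len(dim(data)[1L]))
  new("RoiTimeSeriesBatch", data = data, subjectIds = as.character(subjectIds),
      trSeconds = as.numeric(trSeconds), standardized = FALSE,
      constantRows = matrix(integer(0), 0L, 2L,
                            dimnames = list(NULL, c("subject", "roi"))))
}

#' @describeIn RoiTimeSeriesBatch-class number of subjects S.
#' @param object,x an [RoiTimeSeriesBatch-class].
#' @export
nSubjects <- function(object) dim(object@data)[1L]

#' @describeIn RoiTimeSeriesBatch-class number of ROIs N.
#' @export
nRois <- function(object) dim(object@data)[2L]

#' @describeIn RoiTimeSeriesBatch-class number of time points T.
#' @export
nTimepoints <- function(object) dim(object@data)[3L]

#' @describeIn RoiTimeSeriesBatch-class the `[S, N, T]` data array.
#' @export
batchData <- function(object) object@data

#' @describeIn RoiTimeSeriesBatch-class subject identifiers.
#' @export
subjectIds <- function(object) object@subjectIds

setMethod("show", "RoiTimeSeriesBatch", function(object) {
  d <- dim(object@data)
  cat(sprintf("RoiTimeSeriesBatch: %d subject(s) x %d ROIs x %d time points%s\n",
              d[1L], d[2L], d[3L],
              if (object@standardized) " (standardized)" else ""))
  if (nrow(object@constantRows))
    cat(sprintf("  %d constant ROI row(s) mapped to zero\n", nrow(object@constantRows)))
})

#' ROI to functional-network map
#'
#' Assignment of every ROI to exactly one functional network (seven canonical
#' resting-state systems in the default parcellation).
#'
#' @slot roiToNetwork integer vector length N with values in 1..K.
#' @slot networkNames names of the K networks.
#' @exportClass NetworkMap
setClass("NetworkMap",
  representation(roiToNetwork = "integer", networkNames = "character"),
  validity = function(object) {
    k <- length(object@networkNames)
    if (k < 1L) return("at least one network required")
    if (any(is.na(object@roiToNetwork))) return("every ROI needs a network")
    if (any(object@roiToNetwork < 1L | object@roiToNetwork > k))
      return("roiToNetwork values must index networkNames")
    TRUE
  })

#' Construct a [NetworkMap-class]
#' @param roiToNetwork integer vector, one network index per ROI.
#' @param networkNames optional network names.
#' @return A [NetworkMap-class].
#' @export
networkMap <- function(roiToNetwork, networkNames = NULL) {
  roiToNetwork <- as.integer(roiToNetwork)
  if (is.null(networkNames))
    networkNames <- sprintf("network%d", seq_len(max(roiToNetwork)))
  new("NetworkMap", roiToNetwork = roiToNetwork,
      networkNames = as.character(networkNames))
}

setMethod("show", "NetworkMap", function(object) {
  cat(sprintf("NetworkMap: %d ROIs in %d networks\n",
              length(object@roiToNetwork), length(object@networkNames)))
  print(table(factor(object@roiToNetwork,
                     labels = object@networkNames[sort(unique(object@roiToNetwork))])))
})

#' Learned directed connectivity
#'
#' Row-stochastic N x N attention matrix produced by the node-node
#' self-attention block, together with the per-head matrices it averages. The
#' matrix is generally asymmetric: entry (i, j) is the attention node i pays
#' to node j, read as directed connectivity strength.
#'
#' @slot attFC numeric `[N, N]` row-stochastic matrix.
#' @slot perHead list of per-head `[N, N]` row-stochastic matrices.
#' @exportClass LearnedConnectivity
setClass("LearnedConnectivity",
  representation(attFC = "matrix", perHead = "list"),
  validity = function(object) {
    if (nrow(object@attFC) != ncol(object@attFC)) return("attFC must be square")
    if (max(abs(rowSums(object@attFC) - 1)) > 1e-6)
      return("attFC rows must sum to 1")
    TRUE
  })

#' @describeIn LearnedConnectivity-class the averaged `[N, N]` matrix.
#' @param object a [LearnedConnectivity-class].
#' @export
attFC <- function(object) object@attFC

setMethod("show", "LearnedConnectivity", function(object) {
  n <- nrow(object@attFC)
  asym <- norm(object@attFC - t(object@attFC), "F") / max(norm(object@attFC, "F"), 1e-12)
  cat(sprintf("LearnedConnectivity: %d x %d, %d head(s), relative asymmetry %.3f\n",
              n, n, length(object@perHead), asym))
})

#' Sparse undirected brain graph
#'
#' Graph over ROIs with the learned connectivity rows as node features and the
#' top fraction of correlation edges retained. Edges are stored once with
#' i < j and a signed Pearson r edge weight.
#'
#' @slot nodeFeatures numeric `[N, N]` matrix (rows of the learned connectivity).
#' @slot edges integer `[m, 2]` matrix of (i, j) pairs, i < j.
#' @slot edgeWeights numeric length m, the signed correlations.
#' @slot nNodes integer N.
#' @exportClass BrainGraph
setClass("BrainGraph",
  representation(nodeFeatures = "matrix", edges = "matrix",
                 edgeWeights = "numeric", nNodes = "integer"),
  validity = function(object) {
    if (nrow(object@edges) != length(object@edgeWeights))
      return("one weight per edge required")
    if (nrow(object@edges)) {
      if (any(object@edges[, 1L] >= object@edges[, 2L]))
        return("edges must satisfy i < j (no self-loops)")
      if (max(object@edges) > object@nNodes) return("edge index out of range")
      if (any(!is.finite(object@edgeWeights)) ||
          max(abs(object@edgeWeights)) > 1 + 1e-8)
        return("edge weights must be finite correlations in [-1, 1]")
    }
    TRUE
  })

#' @describeIn BrainGraph-class dense symmetric weighted adjacency matrix.
#' @param object a [BrainGraph-class].
#' @export
adjacencyMatrix <- function(object) {
  A <- matrix(0, object@nNodes, object@nNodes)
  if (nrow(object@edges)) {
    A[object@edges] <- object@edgeWeights
    A[object@edges[, c(2L, 1L), drop = FALSE]] <- object@edgeWeights
  }
  A
}

#' @describeIn BrainGraph-class edge list with weights as a data.frame.
#' @param zeroBased write 0-based node indices (the on-disk convention).
#' @param path optional TSV path; when given the edge list is written as a
#'   3-column (i, j, r) file.
#' @export
edgeList <- function(object, zeroBased = FALSE, path = NULL) {
  off <- if (zeroBased) 1L else 0L
  df <- data.frame(i = object@edges[, 1L] - off, j = object@edges[, 2L] - off,
                   r = object@edgeWeights)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

setMethod("show", "BrainGraph", function(object) {
  cat(sprintf("BrainGraph: %d nodes, %d undirected edges (density %.1f%%)\n",
              object@nNodes, nrow(object@edges),
              100 * nrow(object@edges) / (object@nNodes * (object@nNodes - 1) / 2)))
})

#' Group statistics over learned connectivity
#'
#' Pairwise two-sample t-test results comparing learned connectivity between
#' two subject groups, with per-network significant-node counts.
#'
#' @slot groupMeans list of two `[N, N]` mean matrices.
#' @slot tStat,pValue numeric `[N, N]` matrices (diagonal `NA`).
#' @slot sigMask logical `[N, N]` significance mask after correction.
#' @slot alpha nominal significance level.
#' @slot correction `"bonferroni"` or `"none"`.
#' @slot nTests number of tests corrected for.
#' @exportClass GroupFcStats
setClass("GroupFcStats",
  representation(groupMeans = "list", tStat = "matrix", pValue = "matrix",
                 sigMask = "matrix", alpha = "numeric", correction = "character",
                 nTests = "integer"))

setMethod("show", "GroupFcStats", function(object) {
  ns <- sum(object@sigMask, na.rm = TRUE)
  cat(sprintf(
    "GroupFcStats: %d x %d pairs, %d significant at alpha = %g (%s, %d tests)\n",
    nrow(object@tStat), ncol(object@tStat), ns, object@alpha,
    object@correction, object@nTests))
})

#' Fitted model
#'
#' A trained model: configuration, learned parameters, batch-normalisation
#' running moments, and the training history.
#'
#' @slot config the `dsamConfig` used.
#' @slot params named list of parameter arrays (best validation-loss state).
#' @slot bnStats named list of batch-normalisation running moments.
#' @slot history data.frame with per-epoch loss breakdown.
#' @slot bestEpoch epoch whose parameters are stored.
#' @exportClass DsamFit
setClass("DsamFit",
  representation(config = "list", params = "list", bnStats = "list",
                 history = "data.frame", bestEpoch = "integer"))

setMethod("show", "DsamFit", function(object) {
  cat(sprintf("DsamFit: N = %d, T = %d; %d parameter arrays (%d values); best epoch %d/%d\n",
              object@config$nRois, object@config$tPoints, length(object@params),
              sum(vapply(object@params, length, 1L)), object@bestEpoch,
              nrow(object@history)))
})
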