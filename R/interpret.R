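# Interpretation pipeline: extract the learned connectivity on a holdout set,
# column-normalise it, test every ordered node pair for a group difference,
# correct for multiple comparisons, and summarise significant nodes per
# functional network.

#' Column-normalise connectivity matrices
#'
#' Z-scores each column of each subject's matrix (sample standard deviation),
#' the default normalisation before group comparison; `"minmax"` rescales
#' each column to \[0, 1\] instead.
#'
#' @param mats `[S, N, N]` array of per-subject matrices.
#' @param method `"column_z"` or `"minmax"`.
#' @return Normalised `[S, N, N]` array.
#' @export
normalizeConnectivity <- function(mats, method = c("column_z", "minmax")) {
  method <- match.arg(method)
  out <- mats
  for (s in seq_len(dim(mats)[1L])) {
    m <- mats[s, , ]
    if (method == "column_z") {
      mu <- colMeans(m)
      sdv <- apply(m, 2L, sd)
      sdv[sdv < 1e-12] <- 1
      out[s, , ] <- t((t(m) - mu) / sdv)
    } else {
      lo <- apply(m, 2L, min); hi <- apply(m, 2L, max)
      rg <- hi - lo
      rg[rg < 1e-12] <- 1
      out[s, , ] <- t((t(m) - lo) / rg)
    }
  }
  out
}

#' Extract group-mean learned connectivity from a holdout set
#'
#' Runs the trained temporal and self-attention blocks on the holdout
#' subjects, column-normalises every subject's directed connectivity matrix,
#' and averages within each label group.
#'
#' @param fit a [DsamFit-class].
#' @param batch holdout [RoiTimeSeriesBatch-class] (disjoint from training).
#' @param labels 0/1 labels of the holdout subjects.
#' @param normalize normalisation method, see [normalizeConnectivity()].
#' @return List with `perSubject` (`[S, N, N]` normalised array) and
#'   `groupMeans` (list of two `[N, N]` matrices, groups 0 and 1).
#' @export
extractGroupFc <- function(fit, batch, labels, normalize = "column_z") {
  labels <- checkLabels(labels)
  mats <- normalizeConnectivity(extractConnectivity(fit, batch), normalize)
  list(perSubject = mats,
       groupMeans = lapply(c(0L, 1L), function(g) {
         idx <- which(labels == g)
         if (!length(idx)) stop("empty group ", g)
         apply(mats[idx, , , drop = FALSE], c(2L, 3L), mean)
       }))
}

#' Pairwise two-sample t-tests on connectivity
#'
#' Tests every ordered node pair (i != j) for a mean difference between the
#' two groups. Welch's unequal-variance t-test is the default; the pooled
#' variance form is available. Bonferroni correction multiplies p-values by
#' the number of tests. Pairs with zero variance in both groups get `NA`.
#'
#' @param mats `[S, N, N]` array of per-subject (normalised) matrices.
#' @param labels 0/1 labels of length S.
#' @param alpha nominal significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @param varType `"welch"` or `"pooled"`.
#' @return A [GroupFcStats-class].
#' @export
pairwiseGroupTtests <- function(mats, labels, alpha = 0.05,
                                correction = c("bonferroni", "none"),
                                varType = c("welch", "pooled")) {
  correction <- match.arg(correction)
  varType <- match.arg(varType)
  labels <- checkLabels(labels)
  i0 <- which(labels == 0L); i1 <- which(labels == 1L)
  n0 <- length(i0); n1 <- length(i1)
  if (n0 < 2L || n1 < 2L) stop("each group needs at least 2 subjects")
  N <- dim(mats)[2L]
  m0 <- apply(mats[i0, , , drop = FALSE], c(2L, 3L), mean)
  m1 <- apply(mats[i1, , , drop = FALSE], c(2L, 3L), mean)
  v0 <- apply(mats[i0, , , drop = FALSE], c(2L, 3L), var)
  v1 <- apply(mats[i1, , , drop = FALSE], c(2L, 3L), var)
  if (varType == "welch") {
    se2 <- v0 / n0 + v1 / n1
    df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  } else {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se2 <- sp2 * (1 / n0 + 1 / n1)
    df <- matrix(n0 + n1 - 2, N, N)
  }
  tt <- (m1 - m0) / sqrt(se2)
  tt[se2 < 1e-24] <- NA
  p <- 2 * pt(-abs(tt), df)
  p[is.na(tt)] <- NA
  p[!is.na(tt) & se2 >= 1e-24 & abs(tt) < 1e-300] <- 1
  diag(tt) <- NA
  diag(p) <- NA
  nTests <- N * (N - 1L)
  pAdj <- if (correction == "bonferroni") pmin(p * nTests, 1) else p
  mask <- !is.na(pAdj) & pAdj <= alpha
  new("GroupFcStats",
      groupMeans = list(m0, m1), tStat = tt, pValue = p,
      sigMask = mask, alpha = alpha, correction = correction,
      nTests = as.integer(nTests))
}

#' Per-network counts of significant nodes
#'
#' Counts, for every functional network, the distinct ROIs participating in
#' at least one significant pair.
#'
#' @param stats a [GroupFcStats-class].
#' @param map a [NetworkMap-class].
#' @return Named integer vector, one count per network.
#' @export
networkSummary <- function(stats, map) {
  sig <- which(stats@sigMask, arr.ind = TRUE)
  nodes <- unique(c(sig[, 1L], sig[, 2L]))
  k <- length(map@networkNames)
  counts <- integer(k)
  for (b in seq_len(k)) {
    counts[b] <- sum(map@roiToNetwork[nodes] == b)
  }
  names(counts) <- map@networkNames
  counts
}

#' Write the full interpretation output set
#'
#' Writes the t matrix, p matrix, the significant-pair list (i, j, t, p) and
#' the per-network node-count table as TSV files.
#'
#' @param stats a [GroupFcStats-class].
#' @param map a [NetworkMap-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeGroupFcStats <- function(stats, map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(stats@tStat)
  roi <- sprintf("roi%03d", seq_len(n))
  writeConnectivity(ifelse(is.na(stats@tStat), 0, stats@tStat), roi,
                    file.path(dir, "t_matrix.tsv"))
  writeConnectivity(ifelse(is.na(stats@pValue), 1, stats@pValue), roi,
                    file.path(dir, "p_matrix.tsv"))
  sig <- which(stats@sigMask, arr.ind = TRUE)
  df <- data.frame(i = sig[, 1L], j = sig[, 2L],
                   t = stats@tStat[sig], p = stats@pValue[sig])
  write.table(df[order(df$p), ], file.path(dir, "significant_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- networkSummary(stats, map)
  write.table(data.frame(network = names(counts), significant_nodes = counts),
              file.path(dir, "network_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
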