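# Synthetic two-group cohort generator. Emulates the statistical structure the
# model consumes: N ROIs in functional-network blocks, within/between-network
# correlation, AR(1) temporal autocorrelation, and group differences injected
# on selected correlations (not means), since the model classifies via
# connectivity.

#' Specification of a synthetic two-group cohort
#'
#' @param nPerGroup subjects per group.
#' @param nRois number of ROIs N.
#' @param tPoints time points T.
#' @param networkSizes integer vector of network block sizes, summing to N.
#' @param rhoWithin baseline correlation inside a network block, in \[0, 1).
#' @param rhoBetween baseline correlation between blocks.
#' @param effectEdges data.frame with columns `i`, `j`, `delta`, `group`: the
#'   correlation of edge (i, j) is shifted by `delta` in that group only.
#' @param arCoef AR(1) coefficient phi in (-1, 1).
#' @param seed integer seed.
#' @return A `fixtureSpec` list.
#' @export
fixtureSpec <- function(nPerGroup = 100L, nRois = 50L, tPoints = 200L,
                        networkSizes = c(8L, 7L, 7L, 7L, 7L, 7L, 7L),
                        rhoWithin = 0.3, rhoBetween = 0.05,
                        effectEdges = defaultEffectEdges(networkSizes),
                        arCoef = 0.3, seed = 1L) {
  spec <- list(nPerGroup = as.integer(nPerGroup), nRois = as.integer(nRois),
               tPoints = as.integer(tPoints),
               networkSizes = as.integer(networkSizes),
               rhoWithin = rhoWithin, rhoBetween = rhoBetween,
               effectEdges = effectEdges, arCoef = arCoef,
               seed = as.integer(seed))
  if (sum(spec$networkSizes) != spec$nRois)
    stop("networkSizes must sum to nRois")
  if (!(rhoWithin >= 0 && rhoWithin < 1)) stop("rhoWithin must lie in [0, 1)")
  if (abs(arCoef) >= 1) stop("arCoef must lie in (-1, 1)")
  if (!is.null(effectEdges) && nrow(effectEdges)) {
    stopifnot(all(c("i", "j", "delta", "group") %in% names(effectEdges)),
              all(effectEdges$i != effectEdges$j),
              all(effectEdges$group %in% c(1L, 2L)),
              max(effectEdges$i, effectEdges$j) <= spec$nRois)
  }
  class(spec) <- "fixtureSpec"
  spec
}

#' Default within-network effect edges
#'
#' Picks `nEdges` distinct within-network ROI pairs, cycling over the network
#' blocks, and assigns each a correlation shift of `delta` in group 2.
#'
#' @param networkSizes network block sizes.
#' @param nEdges number of effect edges.
#' @param delta correlation shift.
#' @param group group receiving the shift.
#' @return A data.frame with columns `i`, `j`, `delta`, `group`.
#' @export
defaultEffectEdges <- function(networkSizes, nEdges = 20L, delta = 0.4,
                               group = 2L) {
  starts <- cumsum(c(0L, head(networkSizes, -1L)))
  pairs <- list()
  for (b in seq_along(networkSizes)) {
    n <- networkSizes[b]
    if (n < 2L) next
    idx <- utils::combn(n, 2L)
    pairs[[b]] <- cbind(starts[b] + idx[1L, ], starts[b] + idx[2L, ])
  }
  # interleave across blocks so no single network carries the whole effect
  maxLen <- max(vapply(pairs, nrow, 1L))
  picked <- NULL
  for (r in seq_len(maxLen)) {
    for (b in seq_along(pairs)) {
      if (r <= nrow(pairs[[b]])) picked <- rbind(picked, pairs[[b]][r, ])
      if (!is.null(picked) && nrow(picked) >= nEdges) break
    }
    if (!is.null(picked) && nrow(picked) >= nEdges) break
  }
  if (is.null(picked) || nrow(picked) < nEdges)
    stop("not enough within-network pairs for ", nEdges, " effect edges")
  data.frame(i = picked[, 1L], j = picked[, 2L], delta = delta,
             group = as.integer(group))
}

# Target correlation matrix for one group; shrinks the injected deltas toward
# zero until the matrix is positive definite.
.groupCorrelation <- function(spec, group) {
  n <- spec$nRois
  blocks <- rep(seq_along(spec$networkSizes), spec$networkSizes)
  C <- matrix(spec$rhoBetween, n, n)
  for (b in seq_along(spec$networkSizes)) {
    sel <- blocks == b
    C[sel, sel] <- spec$rhoWithin
  }
  diag(C) <- 1
  eff <- spec$effectEdges
  if (is.null(eff) || !nrow(eff)) eff <- data.frame(i = integer(0))
  shrink <- 1
  for (iter in seq_len(60L)) {
    Cg <- C
    if (nrow(eff)) {
      for (r in seq_len(nrow(eff))) {
        if (eff$group[r] != group) next
        v <- min(max(C[eff$i[r], eff$j[r]] + shrink * eff$delta[r], -0.99), 0.99)
        Cg[eff$i[r], eff$j[r]] <- v
        Cg[eff$j[r], eff$i[r]] <- v
      }
    }
    ev <- eigen(Cg, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8) return(list(C = Cg, shrink = shrink))
    shrink <- shrink * 0.9
  }
  stop("group correlation matrix not positive definite even after shrinking the injected effects")
}

.symSqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a synthetic two-group cohort
#'
#' For every subject, draws a T-step AR(1) process whose innovations carry the
#' group's target cross-ROI correlation (imposed through the symmetric matrix
#' square root), scaled so the stationary covariance equals the target; each
#' ROI row is then z-scored. Group labels are 0 (group 1) and 1 (group 2),
#' balanced. The same seed reproduces the cohort bit for bit.
#'
#' @param spec a [fixtureSpec()].
#' @return A list: `batch` (standardized [RoiTimeSeriesBatch-class]), `labels`
#'   (0/1 integer vector), `map` ([NetworkMap-class]), `trueDiffMask` (N x N
#'   logical marking edges with injected correlation differences between the
#'   groups), `spec`, and `targetCorrelations` (per-group matrices actually
#'   used, after any positive-definiteness shrinkage).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  g1 <- .groupCorrelation(spec, 1L)
  g2 <- .groupCorrelation(spec, 2L)
  L <- list(.symSqrt(g1$C), .symSqrt(g2$C))
  n <- spec$nRois
  Tn <- spec$tPoints
  S <- 2L * spec$nPerGroup
  labels <- rep(c(0L, 1L), each = spec$nPerGroup)
  arr <- array(0, c(S, n, Tn))
  phi <- spec$arCoef
  innovScale <- sqrt(1 - phi^2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  for (s in seq_len(S)) {
    Lg <- L[[labels[s] + 1L]]
    E <- Lg %*% matrix(rnorm(n * Tn), n, Tn)
    X <- matrix(0, n, Tn)
    X[, 1L] <- E[, 1L]
    for (t in 2L:Tn) X[, t] <- phi * X[, t - 1L] + innovScale * E[, t]
    arr[s, , ] <- X
  }
  mask <- abs(g1$C - g2$C) > 1e-12
  diag(mask) <- FALSE
  batch <- standardizeBatch(roiTimeSeriesBatch(arr))
  list(batch = batch, labels = labels,
       map = networkMap(rep(seq_along(spec$networkSizes), spec$networkSizes)),
       trueDiffMask = mask, spec = spec,
       targetCorrelations = list(g1$C, g2$C))
}
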