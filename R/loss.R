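# Composite training objective: cross-entropy plus a per-pooling-layer unit
# loss that keeps each projection vector on the unit sphere, plus a
# lambda-weighted per-layer TopK loss that pushes the sigmoid of the
# normalised scores toward 1 on kept nodes and 0 on dropped ones.
# L_total = L_CE + sum_l L_unit(l) + lambda1 * sum_l L_TPK(l).

#' Unit loss of a pooling projection vector
#'
#' `(||omega||_2 - 1)^2`: zero exactly on the unit sphere. The zero vector is
#' given the value 1 (its limiting value) with a warning.
#'
#' @param omega numeric projection vector.
#' @return Nonnegative scalar.
#' @export
unitLoss <- function(omega) {
  nv <- sqrt(sum(omega^2))
  if (nv < 1e-12) {
    warning("zero projection vector in unit loss")
    return(1)
  }
  (nv - 1)^2
}

#' TopK score-separation loss
#'
#' Binary cross-entropy between the sigmoid of the normalised node scores and
#' the ideal indicator (1 on kept nodes, 0 on dropped ones). Zero in the
#' perfect-separation limit; `log(2)` when all scores are equal.
#'
#' @param scores normalised node scores (length N).
#' @param kept indices of the kept nodes.
#' @return Nonnegative scalar.
#' @export
tpkLoss <- function(scores, kept) {
  target <- as.numeric(seq_along(scores) %in% kept)
  p <- 1 / (1 + exp(-scores))
  -mean(target * log(pmax(p, 1e-12)) + (1 - target) * log(pmax(1 - p, 1e-12)))
}

#' Mean softmax cross-entropy
#'
#' @param logits `[B, 2]` logit matrix (a length-2 vector is taken as B = 1).
#' @param labels 0/1 labels of length B.
#' @return Nonnegative scalar.
#' @export
crossEntropyLoss <- function(logits, labels) {
  if (is.null(dim(logits))) logits <- matrix(logits, 1L)
  P <- softmaxRows(logits)
  Y <- cbind(1 - labels, labels)
  -mean(rowSums(Y * log(pmax(P, 1e-12))))
}

#' Composite loss breakdown
#'
#' @param logits `[B, 2]` logits.
#' @param labels 0/1 labels.
#' @param poolStates list over pooling layers, each a list with `scores` and
#'   `kept` (as produced by [topkPool()]); for a batch, a list over layers of
#'   per-subject lists is also accepted and averaged.
#' @param omegas list of pooling projection vectors, one per layer.
#' @param lambdaTopk weight of the TopK component.
#' @return List with `ce`, `unit` (per layer), `tpk` (per layer) and `total`,
#'   where `total = ce + sum(unit) + lambdaTopk * sum(tpk)` exactly.
#' @export
totalLoss <- function(logits, labels, poolStates, omegas, lambdaTopk = 0.1) {
  ce <- crossEntropyLoss(logits, labels)
  unit <- vapply(omegas, unitLoss, 0)
  tpk <- vapply(poolStates, function(st) {
    if (!is.null(st$scores)) tpkLoss(st$scores, st$kept)
    else mean(vapply(st, function(s1) tpkLoss(s1$scores, s1$kept), 0))
  }, 0)
  list(ce = ce, unit = unit, tpk = tpk,
       total = ce + sum(unit) + lambdaTopk * sum(tpk))
}
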