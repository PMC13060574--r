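# Training: Adam with plateau learning-rate reduction and early stopping,
# stratified k-fold cross-validation, and classification metrics.

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Stratified k-fold split
#'
#' Partitions subjects into k folds preserving class proportions to within
#' one subject per fold; deterministic under the seed.
#'
#' @param labels 0/1 label vector.
#' @param nFolds number of folds.
#' @param seed integer seed.
#' @return List of `nFolds` lists with `train` and `test` index vectors.
#' @export
stratifiedKfold <- function(labels, nFolds = 5L, seed = 1L) {
  labels <- checkLabels(labels)
  if (min(table(labels)) < nFolds)
    stop("each class needs at least ", nFolds, " members")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  lapply(seq_len(nFolds), function(k) {
    list(train = which(fold != k), test = which(fold == k))
  })
}

# Stratified carve-out of a validation fraction from a training index set.
.stratifiedVal <- function(labels, trainIdx, fraction, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  val <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- trainIdx[labels[trainIdx] == cl]
    nv <- max(1L, round(fraction * length(idx)))
    val <- c(val, sample(idx, nv))
  }
  sort(val)
}

#' Classification metrics
#'
#' AUC by the rank statistic (ties averaged), plus accuracy, sensitivity
#' (TP / (TP + FN)) and specificity (TN / (TN + FP)) at a 0.5 threshold on
#' the class-1 probability.
#'
#' @param scores class-1 probabilities (any monotone score works for AUC).
#' @param labels 0/1 labels.
#' @param threshold decision threshold.
#' @return List with `auc`, `accuracy`, `sensitivity`, `specificity` and the
#'   2x2 `confusion` matrix.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- checkLabels(labels)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(auc = auc, accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       confusion = matrix(c(tn, fp, fn, tp), 2L, 2L,
                          dimnames = list(pred = c("0", "1"),
                                          truth = c("0", "1"))))
}

#' Train the model on one split
#'
#' Minibatch Adam under the configured schedule: the learning rate is
#' multiplied by `lrFactor` after `lrPatience` epochs without validation-loss
#' improvement, training stops after `earlyStopPatience` stale epochs or
#' `epochs`, and the parameters with the smallest validation loss are kept.
#'
#' @param batch standardized [RoiTimeSeriesBatch-class].
#' @param labels 0/1 labels.
#' @param cfg the `dsamConfig`.
#' @param trainIdx training subject indices (a validation fraction is carved
#'   out of them, stratified).
#' @param valIdx optional explicit validation indices (disables the carve-out).
#' @param verbose print per-epoch losses.
#' @return A [DsamFit-class].
#' @export
trainDsam <- function(batch, labels, cfg, trainIdx = NULL, valIdx = NULL,
                      verbose = FALSE) {
  labels <- checkLabels(labels)
  xArr <- batchData(batch)
  stopifnot(dim(xArr)[2L] == cfg$nRois, dim(xArr)[3L] == cfg$tPoints)
  trainIdx <- trainIdx %||% seq_len(dim(xArr)[1L])
  if (is.null(valIdx)) {
    valIdx <- .stratifiedVal(labels, trainIdx, cfg$valFraction, cfg$seed + 1L)
    trainIdx <- setdiff(trainIdx, valIdx)
  }
  checkLabels(labels[trainIdx]); checkLabels(labels[valIdx])
  params <- initDsamParams(cfg, cfg$seed)
  bn <- new.env(parent = emptyenv())
  adam <- .adamInit(params)
  cg <- if (cfg$edgeMode == "constant") .constantGraphs(xArr, cfg) else NULL
  lr <- cfg$lr
  best <- list(loss = Inf, params = params, bn = list(), epoch = 0L)
  stale <- 0L
  staleLr <- 0L
  hist <- NULL
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed + 2L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(trainIdx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    comp <- c(ce = 0, unit = 0, tpk = 0, total = 0)
    for (bidx in batches) {
      tp <- tapeNew(training = TRUE)
      pget <- function(nm) tParam(tp, nm, params[[nm]])
      fwd <- .dsamForwardBatch(tp, params, bn, cfg, xArr, bidx, cg)
      ls <- .tTotalLoss(tp, fwd, labels[bidx], cfg, pget)
      if (!is.finite(tVal(tp, ls$total)))
        stop("training diverged: non-finite loss at epoch ", epoch)
      gr <- tapeBackward(tp, ls$total)
      grads <- tapeParamGrads(tp, gr)
      upd <- .adamStep(params, grads, adam, lr)
      params <- upd$params
      adam <- upd$state
      w <- length(bidx) / length(trainIdx)
      comp <- comp + w * c(ls$ce, sum(ls$unit), sum(ls$tpk),
                           tVal(tp, ls$total))
    }
    valLoss <- .evalLoss(params, bn, cfg, xArr, valIdx, labels, cg)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr, ce = comp[1L],
                                   unit = comp[2L], tpk = comp[3L],
                                   train = comp[4L], val = valLoss))
    if (verbose)
      message(sprintf("epoch %3d lr %.1e train %.4f val %.4f", epoch, lr,
                      comp[4L], valLoss))
    if (valLoss < best$loss - 1e-6) {
      best <- list(loss = valLoss, params = params, bn = as.list(bn),
                   epoch = epoch)
      stale <- 0L
      staleLr <- 0L
    } else {
      stale <- stale + 1L
      staleLr <- staleLr + 1L
      if (staleLr >= cfg$lrPatience) {
        lr <- lr * cfg$lrFactor
        staleLr <- 0L
      }
      if (stale >= cfg$earlyStopPatience) break
    }
  }
  rownames(hist) <- NULL
  new("DsamFit", config = unclass(cfg), params = best$params,
      bnStats = best$bn, history = hist, bestEpoch = best$epoch)
}

# Eval-mode composite loss over an index set.
.evalLoss <- function(params, bn, cfg, xArr, idx, labels, cg) {
  tot <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / cfg$batchSize))) {
    tp <- tapeNew(training = FALSE)
    pget <- function(nm) tParam(tp, nm, params[[nm]])
    fwd <- .dsamForwardBatch(tp, params, bn, cfg, xArr, chunk, cg)
    ls <- .tTotalLoss(tp, fwd, labels[chunk], cfg, pget)
    tot <- tot + tVal(tp, ls$total) * length(chunk)
  }
  tot / length(idx)
}

#' Train and evaluate one cross-validation fold
#'
#' @inheritParams trainDsam
#' @param testIdx held-out test indices.
#' @return List with `fit` ([DsamFit-class]), `metrics` (see
#'   [computeMetrics()]), `scores` and `testIdx`.
#' @export
trainFold <- function(batch, labels, cfg, trainIdx, testIdx, verbose = FALSE) {
  fit <- trainDsam(batch, labels, cfg, trainIdx = trainIdx, verbose = verbose)
  sub <- roiTimeSeriesBatch(batchData(batch)[testIdx, , , drop = FALSE],
                            subjectIds = subjectIds(batch)[testIdx])
  sub@standardized <- batch@standardized
  scores <- predictDsam(fit, sub, cfg$batchSize)
  list(fit = fit, metrics = computeMetrics(scores, labels[testIdx]),
       scores = scores, testIdx = testIdx)
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold and reports per-fold and mean +/- sd metrics
#' (as fractions in \[0, 1\]).
#'
#' @inheritParams trainDsam
#' @param nFolds number of folds.
#' @return List with `folds` (per-fold results) and `summary` (data.frame of
#'   mean and sd per metric).
#' @export
crossValidate <- function(batch, labels, cfg, nFolds = 5L, verbose = FALSE) {
  splits <- stratifiedKfold(labels, nFolds, cfg$seed)
  folds <- lapply(seq_along(splits), function(k) {
    r <- trainFold(batch, labels, cfg, splits[[k]]$train, splits[[k]]$test,
                   verbose = verbose)
    r$fold <- k
    r
  })
  m <- sapply(folds, function(f) unlist(f$metrics[c("auc", "accuracy",
                                                    "sensitivity", "specificity")]))
  list(folds = folds,
       summary = data.frame(metric = rownames(m), mean = rowMeans(m),
                            sd = apply(m, 1L, sd), row.names = NULL))
}
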