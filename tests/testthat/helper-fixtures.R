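# Shared fixtures, built once per test run.

.cacheEnv <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.cacheEnv[[key]])) .cacheEnv[[key]] <- fn()
  .cacheEnv[[key]]
}

# Small configuration + parameter set used by most structural tests.
tinyConfig <- function(...) {
  args <- list(nRois = 10L, tPoints = 60L, batchSize = 4L, dropout = 0,
               epochs = 3L)
  do.call(dsamConfig, utils::modifyList(args, list(...)))
}

tinyParams <- function(cfg = tinyConfig(), seed = 1L) {
  initDsamParams(cfg, seed)
}

tinyCohort <- function() {
  memo("tinyCohort", function() {
    generateCohort(fixtureSpec(
      nPerGroup = 10L, nRois = 10L, tPoints = 60L,
      networkSizes = c(5L, 5L),
      effectEdges = defaultEffectEdges(c(5L, 5L), nEdges = 4L, delta = 0.4),
      seed = 3L))
  })
}

# The separable desk-scale cohort and its single trained fold, shared between
# the end-to-end tests (training once keeps the suite fast).
sanityCohort <- function() {
  memo("sanityCohort", function() generateCohort(fixtureSpec(seed = 101L)))
}

sanityConfig <- function(seed = 11L) {
  dsamConfig(nRois = 50L, tPoints = 200L, epochs = 16L, lr = 3e-3,
             batchSize = 8L, lrPatience = 5L, earlyStopPatience = 7L,
             dropout = 0.1, edgeMode = "constant", seed = seed)
}

sanityFold <- function() {
  memo("sanityFold", function() {
    co <- sanityCohort()
    folds <- stratifiedKfold(co$labels, 5L, 11L)
    trainFold(co$batch, co$labels, sanityConfig(), folds[[1L]]$train,
              folds[[1L]]$test)
  })
}

# End-to-end training loss for finite-difference gradient checks.
endToEndLoss <- function(params, cfg, xArr, labels, idx) {
  bn <- new.env(parent = emptyenv())
  tp <- dsam:::tapeNew(training = TRUE)
  pget <- function(nm) dsam:::tParam(tp, nm, params[[nm]])
  fwd <- dsam:::.dsamForwardBatch(tp, params, bn, cfg, xArr, idx, NULL)
  ls <- dsam:::.tTotalLoss(tp, fwd, labels[idx], cfg, pget)
  dsam:::tVal(tp, ls$total)
}

endToEndGrads <- function(params, cfg, xArr, labels, idx) {
  bn <- new.env(parent = emptyenv())
  tp <- dsam:::tapeNew(training = TRUE)
  pget <- function(nm) dsam:::tParam(tp, nm, params[[nm]])
  fwd <- dsam:::.dsamForwardBatch(tp, params, bn, cfg, xArr, idx, NULL)
  ls <- dsam:::.tTotalLoss(tp, fwd, labels[idx], cfg, pget)
  list(loss = dsam:::tVal(tp, ls$total),
       grads = dsam:::tapeParamGrads(tp, dsam:::tapeBackward(tp, ls$total)),
       fwd = fwd, tp = tp)
}
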