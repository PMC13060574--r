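#' Model and training configuration
#'
#' Builds the configuration list that controls every stage of the model: the
#' temporal convolution stack, the shared temporal attention block with top-K
#' time-point selection, the node-node self-attention block, graph
#' construction, the relational graph-isomorphism layers with TopK pooling,
#' the classification head, the composite loss, and the training schedule.
#'
#' Defaults follow the reference study configuration: kernel size 7 with
#' channels 8/16/32 and dilations 1/2/4 over three blocks, 4 temporal
#' attention heads, selection threshold `th = 0.1`, 3 spatial heads with
#' embedding size 64, 30% edge retention, two 32-unit graph layers with
#' pooling ratio 0.5 and 7 learned clusters, a \[32, 512\] fully connected
#' head, `lambdaTopk = 0.1`, 150 epochs with batch size 32, learning-rate
#' reduction by 0.1 after 30 stale epochs and early stopping after 40.
#'
#' @param nRois number of ROIs (graph nodes) N.
#' @param tPoints number of time points T per ROI.
#' @param kernelSize convolution kernel size K.
#' @param channels integer triple: channels of the three temporal blocks.
#' @param dilations integer triple, must equal `2^(l-1)`.
#' @param temporalHeads heads of the shared temporal attention block.
#' @param temporalEmbed total query/key embedding width of the temporal block.
#' @param topkThreshold fraction `th` of time points kept per level, in (0,1].
#' @param spatialHeads heads of the connectivity self-attention block (one per
#'   temporal level in the default configuration).
#' @param spatialEmbed per-head query/key embedding size of the spatial block.
#' @param edgeMode `"dynamic"` (correlation of the selected temporal features,
#'   recomputed every forward pass) or `"constant"` (correlation of the raw
#'   time series, fixed per subject).
#' @param edgeKeepFraction fraction of undirected edges retained.
#' @param rankEdgesBy `"abs"` ranks candidate edges by |r|, `"signed"` by r.
#' @param rginDims output widths of the two graph convolution layers.
#' @param poolingRatio TopK pooling keep ratio k in (0,1].
#' @param nClusters number of learned ROI clusters K_cl.
#' @param mlpDims hidden widths of the classification head, applied in
#'   order (readout -> mlpDims\[1\] -> mlpDims\[2\] -> 2).
#' @param lambdaTopk weight of the TopK score-separation loss.
#' @param dropout dropout rate inside the temporal blocks.
#' @param scoreMode time-point scoring rule: `"attention"` (column sums of the
#'   head-averaged attention matrix, i.e. attention received) or
#'   `"magnitude"` (mean absolute attended feature value per time point).
#' @param epochs,batchSize,lr,lrFactor,lrPatience,earlyStopPatience,valFraction
#'   training schedule: maximum epochs, minibatch size, initial Adam learning
#'   rate, multiplicative learning-rate factor applied after `lrPatience`
#'   epochs without validation improvement, early stop after
#'   `earlyStopPatience` stale epochs, and the stratified fraction of the
#'   training portion held out for validation.
#' @param sdType `"population"` or `"sample"` standard deviation for z-scoring.
#' @param seed integer seed controlling initialisation and batching.
#' @param ... overrides stored verbatim (unknown names are rejected).
#' @return A validated `dsamConfig` list.
#' @export
dsamConfig <- function(nRois = 100L, tPoints = 1200L, kernelSize = 7L,
                       channels = c(8L, 16L, 32L), dilations = c(1L, 2L, 4L),
                       temporalHeads = 4L, temporalEmbed = 64L,
                       topkThreshold = 0.1, spatialHeads = 3L,
                       spatialEmbed = 64L, edgeMode = c("dynamic", "constant"),
                       edgeKeepFraction = 0.30, rankEdgesBy = c("abs", "signed"),
                       rginDims = c(32L, 32L), poolingRatio = 0.5,
                       nClusters = 7L, mlpDims = c(32L, 512L),
                       lambdaTopk = 0.1, dropout = 0.1,
                       scoreMode = c("attention", "magnitude"),
                       epochs = 150L, batchSize = 32L, lr = 1e-3,
                       lrFactor = 0.1, lrPatience = 30L,
                       earlyStopPatience = 40L, valFraction = 0.2,
                       sdType = c("population", "sample"), seed = 1L, ...) {
  cfg <- list(
    nRois = as.integer(nRois), tPoints = as.integer(tPoints),
    kernelSize = as.integer(kernelSize), channels = as.integer(channels),
    dilations = as.integer(dilations), temporalHeads = as.integer(temporalHeads),
    temporalEmbed = as.integer(temporalEmbed),
    topkThreshold = topkThreshold, spatialHeads = as.integer(spatialHeads),
    spatialEmbed = as.integer(spatialEmbed), edgeMode = match.arg(edgeMode),
    edgeKeepFraction = edgeKeepFraction, rankEdgesBy = match.arg(rankEdgesBy),
    rginDims = as.integer(rginDims), poolingRatio = poolingRatio,
    nClusters = as.integer(nClusters), mlpDims = as.integer(mlpDims),
    lambdaTopk = lambdaTopk, dropout = dropout,
    scoreMode = match.arg(scoreMode), epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), lr = lr, lrFactor = lrFactor,
    lrPatience = as.integer(lrPatience),
    earlyStopPatience = as.integer(earlyStopPatience),
    valFraction = valFraction, sdType = match.arg(sdType), seed = as.integer(seed))
  extra <- list(...)
  if (length(extra)) {
    bad <- setdiff(names(extra), names(cfg))
    if (length(bad)) stop("unknown configuration fields: ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, extra)
  }
  validateConfig(cfg)
  class(cfg) <- "dsamConfig"
  cfg
}

validateConfig <- function(cfg) {
  stopifnot(cfg$nRois >= 2L, cfg$tPoints >= 2L, cfg$kernelSize >= 1L,
            length(cfg$channels) == 3L, all(cfg$channels >= 1L),
            length(cfg$dilations) == 3L)
  if (!all(cfg$dilations == 2L^(seq_len(3L) - 1L)))
    stop("dilations must follow d = 2^(l-1), i.e. 1, 2, 4")
  if (!(cfg$topkThreshold > 0 && cfg$topkThreshold <= 1))
    stop("topkThreshold must lie in (0, 1]")
  if (!(cfg$edgeKeepFraction > 0 && cfg$edgeKeepFraction <= 1))
    stop("edgeKeepFraction must lie in (0, 1]")
  if (!(cfg$poolingRatio > 0 && cfg$poolingRatio <= 1))
    stop("poolingRatio must lie in (0, 1]")
  if (floor(cfg$tPoints * cfg$topkThreshold) < 1)
    stop("topkThreshold keeps zero time points at T = ", cfg$tPoints)
  if (cfg$temporalEmbed %% cfg$temporalHeads != 0L)
    stop("temporalEmbed must be divisible by temporalHeads")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' The YAML file mirrors the `dsamConfig` field names.
#' @param path file path.
#' @param cfg a `dsamConfig`.
#' @return `loadConfig` returns a `dsamConfig`; `saveConfig` returns `path`.
#' @export
loadConfig <- function(path) {
  do.call(dsamConfig, yaml::read_yaml(path))
}

#' @rdname loadConfig
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.dsamConfig <- function(x, ...) {
  cat("dsam model configuration\n")
  cat(sprintf("  N = %d ROIs, T = %d time points\n", x$nRois, x$tPoints))
  cat(sprintf("  TCN: kernel %d, channels %s, dilations %s, dropout %.2f\n",
              x$kernelSize, paste(x$channels, collapse = "/"),
              paste(x$dilations, collapse = "/"), x$dropout))
  cat(sprintf("  temporal attention: %d heads, embed %d, th = %.2f (%d kept/level)\n",
              x$temporalHeads, x$temporalEmbed, x$topkThreshold,
              floor(x$tPoints * x$topkThreshold)))
  cat(sprintf("  spatial attention: %d heads, embed %d\n", x$spatialHeads, x$spatialEmbed))
  cat(sprintf("  graph: %s edges, keep %.0f%%, RGIN %s, pool %.2f, %d clusters\n",
              x$edgeMode, 100 * x$edgeKeepFraction,
              paste(x$rginDims, collapse = "/"), x$poolingRatio, x$nClusters))
  cat(sprintf("  training: %d epochs, batch %d, lr %.2g, lambdaTopk %.2g\n",
              x$epochs, x$batchSize, x$lr, x$lambdaTopk))
  invisible(x)
}
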