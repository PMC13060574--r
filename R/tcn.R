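# Multi-level dilated causal convolution stack. Three blocks of two
# convolution layers each (conv -> batch norm -> rectifier -> dropout), one
# dilation per block (1, 2, 4), then a per-block 1x1 convolution collapsing
# the channels to a single feature series per ROI. Strict causality comes from
# implicit left zero padding of (K-1)*d; no residual connections inside a
# block.

# Internal stacked forward. x is a (B*T) x Cin node (series-contiguous rows);
# returns list(levels = list of (B*T) x 1 nodes, last = final block output).
.tTcnStack <- function(tp, x, pget, cfg, Tlen, bnState) {
  levels <- vector("list", 3L)
  cur <- x
  for (l in 1:3) {
    d <- cfg$dilations[l]
    for (j in 1:2) {
      pre <- sprintf("tcn.b%d.c%d", l, j)
      cur <- tDilConv(tp, cur, pget(paste0(pre, ".W")), pget(paste0(pre, ".b")),
                      d, Tlen)
      cur <- tBnReluDrop(tp, cur, pget(paste0(pre, ".g")),
                         pget(paste0(pre, ".be")), pre, bnState, cfg$dropout)
    }
    col <- tAddBias(tp, tMatmul(tp, cur, pget(sprintf("tcn.b%d.col.W", l))),
                    pget(sprintf("tcn.b%d.col.b", l)))
    levels[[l]] <- col
  }
  list(levels = levels, last = cur)
}

#' Dilated causal convolution
#'
#' Convolves each input channel series with a bank of causal dilated filters:
#' `y[o, t] = bias[o] + sum_{c,s} W[s, c, o] * x[c, t - d*s]`, with zero
#' padding on the left so the output at time t depends only on inputs at
#' times <= t and the temporal length is preserved.
#'
#' @param x numeric `[Cin, T]` matrix (or a length-T vector for Cin = 1).
#' @param W `[K, Cin, Cout]` filter array (or a length-K vector for a single
#'   in/out channel).
#' @param d dilation factor, a positive integer.
#' @param bias optional length-Cout bias.
#' @return `[Cout, T]` matrix.
#' @export
dilatedCausalConv <- function(x, W, d = 1L, bias = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (is.null(dim(W))) W <- array(W, c(length(W), 1L, 1L))
  d <- as.integer(d)
  K <- dim(W)[1L]
  if (d < 1L || K < 1L) stop("kernel size and dilation must be positive")
  if (dim(W)[2L] != nrow(x)) stop("input channels (", nrow(x),
                                  ") do not match filter channels (", dim(W)[2L], ")")
  Tlen <- ncol(x)
  if (is.null(bias)) bias <- numeric(dim(W)[3L])
  y <- dsam_conv_fwd(t(x), as.numeric(W), K, dim(W)[2L], dim(W)[3L],
                     as.integer(Tlen), d, bias)
  t(y)
}

#' Run one temporal convolution block
#'
#' Applies the block's two layers (convolution, batch normalisation,
#' rectifier, dropout) to a multi-channel input. In eval mode (`training =
#' FALSE`, the default) dropout is inert and batch normalisation uses the
#' supplied running moments, so the output is deterministic.
#'
#' @param x `[Cin, T]` input matrix.
#' @param params named parameter list of a fitted or initialised model.
#' @param block block index 1..3 (fixes the dilation 2^(l-1)).
#' @param cfg the `dsamConfig`.
#' @param bnStats list of batch-normalisation running moments (defaults to
#'   fresh moments: mean 0, variance 1).
#' @param training logical; batch statistics and live dropout when `TRUE`.
#' @return `[Cout, T]` matrix with the block's channel count.
#' @export
runTcnBlock <- function(x, params, block, cfg, bnStats = NULL, training = FALSE) {
  tp <- tapeNew(training = training)
  bn <- as.environment(bnStats %||% list())
  pget <- function(nm) tParam(tp, nm, params[[nm]])
  cur <- tConst(tp, t(x))
  d <- cfg$dilations[block]
  for (j in 1:2) {
    pre <- sprintf("tcn.b%d.c%d", block, j)
    if (is.null(params[[paste0(pre, ".W")]])) stop("missing parameters for block ", block)
    if (dim(params[[paste0(pre, ".W")]])[2L] != ncol(tVal(tp, cur)))
      stop("channel mismatch entering block ", block)
    cur <- tDilConv(tp, cur, pget(paste0(pre, ".W")), pget(paste0(pre, ".b")), d, ncol(x))
    cur <- tBnReluDrop(tp, cur, pget(paste0(pre, ".g")), pget(paste0(pre, ".be")),
                       pre, bn, cfg$dropout)
  }
  t(tVal(tp, cur))
}

#' Encode a subject into three temporal feature levels
#'
#' Cascades the three dilated causal blocks (d = 1, 2, 4) and collapses each
#' block's channels with its own 1x1 convolution, yielding three `[N, T]`
#' single-channel feature levels per subject.
#'
#' @param x `[N, T]` standardized ROI time-series matrix.
#' @param params named parameter list (see [initDsamParams()]).
#' @param cfg the `dsamConfig`.
#' @param bnStats optional running batch-normalisation moments.
#' @param training logical, see [runTcnBlock()].
#' @return List of three `[N, T]` matrices (low, medium, high level).
#' @export
encodeMultilevel <- function(x, params, cfg, bnStats = NULL, training = FALSE) {
  tp <- tapeNew(training = training)
  bn <- as.environment(bnStats %||% list())
  pget <- function(nm) tParam(tp, nm, params[[nm]])
  N <- nrow(x); Tlen <- ncol(x)
  x0 <- tConst(tp, matrix(as.vector(t(x)), ncol = 1L))
  st <- .tTcnStack(tp, x0, pget, cfg, Tlen, bn)
  lapply(st$levels, function(id) {
    matrix(tVal(tp, id)[, 1L], N, Tlen, byrow = TRUE)
  })
}
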