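---
title: "Learning goal-specific brain connectivity from ROI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning goal-specific brain connectivity from ROI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dsam)
```

## The model

Most resting-state fMRI classification pipelines first collapse the ROI time
series into a static functional-connectivity (FC) matrix — typically Pearson
correlation — and only then fit a classifier. `dsam` implements the opposite
philosophy: the connectivity matrix is itself *learned*, end to end, as part
of a classification network, so the estimated connections are the ones that
matter for the prediction task. The architecture has four stages:

1. **Multi-level temporal encoding.** Each ROI's z-scored series
   $t_i \in \mathbb{R}^T$ passes through three blocks of dilated causal
   convolutions,
   $(t_i * f)(t) = \sum_{s=0}^{K-1} f(s)\, t_i(t - d s)$,
   with kernel size $K = 7$, channels 8/16/32 and dilations $d = 2^{l-1} =
   1, 2, 4$. Each block applies two convolution layers, each followed by
   batch normalisation, a rectifier and dropout; causality comes from left
   zero padding of $(K-1)d$, so temporal length is preserved and the output
   at time $t$ never sees the future. After each block a block-specific
   $1{\times}1$ convolution collapses the channels to one, giving three
   feature levels $\tilde T_1, \tilde T_2, \tilde T_3 \in
   \mathbb{R}^{N \times T}$ at increasing temporal abstraction (cumulative
   receptive field $1 + \sum_l 2(K-1)d_l = 85$ samples at level three).

2. **Shared temporal attention with top-K time-point selection.** One
   attention parameter set serves all three levels, encouraging a coherent
   choice of salient time points. Tokens are time points; the token at time
   $t$ carries the $N$-vector of ROI features. Queries and keys project to a
   64-dimensional embedding split over 4 heads; the head-averaged
   $T \times T$ row-stochastic attention matrix produces the attended output
   (through an $N \times N$ value map, a residual connection and per-token
   layer normalisation). Time point $t$ is scored by the total attention it
   *receives* — the $t$-th column sum of the attention matrix — and the top
   $\lfloor T\,th \rfloor$ time points per level are kept, in temporal
   order, with $th = 0.1$ (120 of 1200 per level, 360 of 3600 in total at
   the reference configuration). The three selections are concatenated into
   $\hat T \in \mathbb{R}^{N \times 3\lfloor T\,th\rfloor}$.

3. **Node–node self-attention: the learned directed FC.** The feature vector
   of each ROI is divided into contiguous per-head slices *first* (one per
   temporal level, $H = 3$), then each head embeds its slice into keys and
   queries of size 64 and forms a softmax-normalised $N \times N$ attention
   matrix; the heads are averaged into `AttFC`. Every row sums to one, and
   the matrix is generally asymmetric: entry $(i, j)$ is read as directed
   connectivity from ROI $i$ to ROI $j$. `AttFC` doubles as the node-feature
   matrix of the graph stage.

4. **ROI-aware graph classification.** An undirected graph is built by
   keeping the top 30% of node pairs ranked by absolute Pearson correlation
   between feature rows — of $\hat T$ in *dynamic* mode (recomputed every
   forward pass, so the graph co-evolves with the attention) or of the raw
   series in *constant* mode — with the signed correlation as edge weight.
   Two relational graph-isomorphism (RGIN) layers of width 32 update node
   $i$ as
   $h_i' = \mathrm{MLP}\big((1+\epsilon)\,W_i h_i + \sum_j e_{ij} W_j h_j\big)$,
   where $W_i = \sum_{u=1}^{K_{cl}} \alpha_{iu} \beta_u + b$ mixes
   $K_{cl} = 7$ shared basis matrices by learned nonnegative cluster
   assignments $\alpha_i = \mathrm{relu}(\theta_1[i,])$ — one row per ROI,
   so the convolution is ROI-aware while using far fewer parameters than
   $N$ full matrices. After each layer, TopK pooling scores nodes by a
   normalised learnable projection, z-normalises the scores, keeps the top
   $\lceil kN \rceil$ nodes ($k = 0.5$) and gates the kept features by the
   sigmoid of their scores. Mean and max summaries of both pooled layers
   are concatenated (128 values) and classified by a fully connected head
   with hidden sizes 32 and 512.

Training minimises
$L = L_{CE} + \sum_l L_{unit}^{(l)} + \lambda_1 \sum_l L_{TPK}^{(l)}$
with $\lambda_1 = 0.1$: cross-entropy, a unit loss
$(\lVert\omega^{(l)}\rVert_2 - 1)^2$ keeping each pooling projection on the
unit sphere, and a TopK loss (binary cross-entropy of the sigmoid scores
against the kept/dropped indicator) that pushes selected and unselected
node scores apart.

## Decisions where the design was open

Several details are not fixed by the architecture's definition; the package
makes the following choices, each switchable where noted:

* **Time-point scoring rule.** The ranking statistic behind the temporal
  top-K is not specified. The default scores a time point by the attention
  it receives (column sums of the head-averaged attention matrix), the
  standard importance reading of an attention matrix; an alternative based
  on attended-feature magnitude is available via `scoreMode = "magnitude"`.
  Floor is used for the kept count, ties break toward the earlier time
  point, and kept columns are restored to temporal order.
* **Head combination.** Whether the four temporal heads are averaged or
  concatenated-then-projected before the residual is unspecified; the
  package averages the head attention matrices and applies a single value
  map, which keeps the scored matrix and the output path consistent.
* **Layer normalisation axis.** Applied per time token across the N ROI
  features, with learnable gain and bias, matching the token reading of the
  residual unit.
* **Attention embedding.** The temporal block's query/key embedding size is
  unstated; 64 (4 heads of 16) mirrors the spatial block's embedding size.
* **No value matrix in the spatial block.** The learned FC is built from
  keys and queries only: no value projection enters the averaged attention
  matrix, which is itself the output.
* **RGIN update.** The 2-layer MLP is applied to the full aggregate (self
  term plus neighbour sum), the graph-isomorphism convention; applying it
  to the self term alone would break the K_cl = 1 reduction to a plain GIN
  update.
  The basis bias $b$ is a $d_{out} \times d_{in}$ matrix, which keeps the
  layer's learnable parameter count at $K_{cl} d_{out} d_{in} + N K_{cl} +
  d_{out} d_{in}$ — the point of the basis decomposition.
* **Cluster assignments after pooling.** Assignment rows are indexed by
  *original* ROI identity at every layer and subset to surviving nodes.
  Indexing by pooled slot would make the model depend on node labelling
  order, breaking relabeling equivariance (verified in the tests: permuting
  ROIs together with their position encodings leaves the logits unchanged).
* **Edge ranking.** The 30% retention is global over node pairs and ranks
  by |r| (anticorrelation is informative in rs-fMRI); the signed value is
  kept as the edge feature. `rankEdgesBy = "signed"` switches the ranking.
* **Head order.** The reference fully connected sizes [32, 512] are
  applied in that order (readout 128 → 32 → 512 → 2), odd as the widening
  is; the sizes are configurable through `mlpDims`.
* **Degenerate pooling scores.** If all node scores are equal the
  z-normalised scores are defined as zero and the lowest-index nodes are
  kept, so pooling is total.
* **TopK loss form.** The score-separation loss is the sorted-sigmoid
  binary cross-entropy adopted from the ROI-selection literature the
  architecture builds on; the defining publication delegates the form.
* **Tie-breaks** everywhere (time points, edges, pooled nodes) resolve
  toward the lower index, making every discrete selection deterministic.

## What the synthetic cohorts emulate

`fixtureSpec()`/`generateCohort()` produce two-group cohorts with the
statistical structure the model consumes: N ROIs partitioned into 7
functional-network blocks, within-network correlation `rhoWithin` (default
0.3) against a between-network floor (0.05), AR(1) temporal autocorrelation
(`arCoef` = 0.3, a minimal stand-in for the smoothness of BOLD), and a
*connectivity* group difference: selected within-network edges are shifted
by `delta` (default +0.4 on 20 edges in group 2, interleaved across
networks). Cross-ROI covariance is imposed on the innovations through the
symmetric matrix square root, so the stationary covariance equals the
target; if an injected shift makes the target indefinite it is shrunk
toward zero until positive definite. Group differences are injected on
correlations rather than means deliberately: the architecture classifies
through connectivity, so the test signal matches the mechanism under test.

The default cohort (100 subjects per group, N = 50, T = 200) is the
package's desk-scale reference: large enough that a separable connectivity
difference is learnable on one CPU in minutes, small enough for routine
testing. What generated cohorts do *not* contain: hemodynamic response
shapes, physiological noise, scanner drift, motion artefacts, or
between-site heterogeneity — so green tests demonstrate the machinery
learns planted connectivity structure, not that it reaches any particular
accuracy on real imaging data.

## Numerical implementation

No deep-learning framework is available to R in this package's dependency
footprint, so the network is trained with the package's own reverse-mode
automatic differentiation: a linear tape over dense matrices whose every
backward rule is validated against central finite differences in the test
suite. The hot paths — dilated causal convolution over the stacked batch,
the fused batch-norm/rectifier/dropout pass, and the temporal attention
level — are C++ kernels (strided BLAS calls; the attention backward
recomputes per-head softmaxes rather than storing them). Batch
normalisation uses population batch statistics with running moments
(momentum 0.1) for evaluation; dropout is inverted and seeded from R's RNG,
so a fixed seed reproduces a training run bit for bit on one machine.
Z-scoring uses the population (1/T) standard deviation by default
(`sdType` switches to 1/(T-1)).

Optimisation is Adam (0.9/0.999) at `lr = 1e-3` with the reference
schedule: multiply by 0.1 after `lrPatience` epochs without validation
improvement, stop after `earlyStopPatience` stale epochs, keep the
best-validation-loss parameters, batch size 32. The validation split is a
stratified 20% of each fold's training portion (its construction is not
otherwise pinned down). Sensitivity and specificity use a
0.5 threshold on the class-1 probability; AUC is the rank statistic.

At desk scale the package's own reference runs (tests and the acceptance
script) use the default cohort with the constant-edge variant, 16 epochs,
`lr = 3e-3`, minibatches of 8 (so 16 optimizer steps per epoch at 128
training subjects), learning-rate patience 5 and early-stop patience 7.
These are desk-scale choices, made once: the planted effect is a
correlation difference, which enters the constant-edge graph directly
through the raw-series Pearson weights, so that variant converges within
minutes of CPU time, whereas the dynamic-edge variant — whose edge weights
come from the still-untrained temporal features — needs far more optimizer
steps than a desk run provides before its attention stages expose the same
structure. The reference 150-epoch/batch-32 schedule and the dynamic edge
mode remain the configuration defaults.

## Interpretation pipeline

`extractConnectivity()` runs the trained attention stages on a holdout set
and returns each subject's directed `AttFC`; matrices are z-normalised per
column (`"minmax"` available), averaged per group, and every *ordered* node
pair (the matrix is directed; the symmetric option is a config away) is
tested with Welch's two-sample t-test (`varType = "pooled"` available),
Bonferroni-corrected by default. Zero-variance pairs report `NA`.
`networkSummary()` counts the distinct ROIs participating in at least one
significant pair per functional network. The nominal level is an argument
throughout — the package hard-codes no threshold.

## Known limitations

* Training cost grows linearly in subjects and roughly linearly in T (the
  attention stage is $O(T^2)$ per subject per level); the reference
  configuration (N = 100, T = 1200) trains, but is sized for GPU-scale
  studies, not a single CPU.
* The learned FC is attention-derived, not a lagged/causal estimate;
  directedness reflects asymmetric attention, not temporal precedence.
* Discrete selections (time points, edges, pooled nodes) pass gradients
  only through the surviving elements.
* Batch-norm statistics couple time points within a training batch;
  strict causality holds exactly in evaluation mode (running moments).
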