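# dsam

Goal-specific brain connectivity, learned end to end from resting-state fMRI
time series.

Classical rs-fMRI analyses compress each subject's ROI time series into a
static Pearson functional-connectivity (FC) matrix before any modelling,
discarding temporal dynamics and fixing the connectivity estimate
independently of the scientific question. `dsam` implements a dynamic
spatio-temporal attention architecture that goes the other way: a directed
connectivity matrix is *learned* inside a classification network, so the
estimated connections are the ones that carry task-relevant signal. For ROI
time series $t_i \in \mathbb{R}^T$ the model stacks

1. three blocks of **dilated causal convolutions**
   $(t_i * f)(t) = \sum_{s=0}^{K-1} f(s)\,t_i(t - ds)$ with $K = 7$,
   channels 8/16/32 and dilations $d = 1, 2, 4$, giving three feature
   levels per ROI;
2. a **shared temporal attention** block (4 heads) whose $T \times T$
   attention matrix scores time points by the attention they receive; only
   the top $\lfloor T \cdot th \rfloor$ time points per level survive
   ($th = 0.1$: 120 of 1200 per level at the reference configuration);
3. a **node–node self-attention** block (3 heads, one per temporal level)
   producing the row-stochastic directed matrix
   $\mathrm{AttFC} = \tfrac1H \sum_h \mathrm{softmax}(Q_h K_h^\top /
   \sqrt{d})$ — the learned FC, which doubles as the graph's node features;
4. a **relational graph-isomorphism network** over the 30%-densest
   correlation graph: per-node weights $W_i = \sum_u \alpha_{iu}\beta_u + b$
   mix 7 shared basis matrices by learned nonnegative ROI-cluster
   assignments, with TopK pooling (ratio 0.5), mean/max readout and a
   fully connected head.

Training minimises cross-entropy plus per-layer unit and TopK
score-separation losses
($L = L_{CE} + \sum_l L_{unit} + \lambda_1 \sum_l L_{TPK}$,
$\lambda_1 = 0.1$) under Adam with plateau learning-rate decay and early
stopping, evaluated by stratified k-fold cross-validation (AUC, accuracy,
sensitivity, specificity). A group-difference pipeline extracts the learned
FC on a holdout set, column-normalises it, runs Welch t-tests on every
ordered ROI pair with Bonferroni correction, and summarises significant
nodes per functional network.

The package is aimed at methods researchers who want a fully inspectable,
CPU-trainable implementation of learned-connectivity classification: every
stage is exposed as a documented function, the network is trained by the
package's own finite-difference-validated reverse-mode autodiff (C++
kernels for the convolution and attention hot paths), and a synthetic
cohort generator with planted connectivity differences makes the entire
pipeline testable without imaging data.

## Worked example

Generate a two-group synthetic cohort (100 subjects per group, 50 ROIs in
seven network blocks, T = 200, twenty within-network edges whose
correlation is 0.4 higher in group 2), train on one stratified fold, and
test the learned connectivity for group differences:

```r
library(dsam)

spec <- fixtureSpec(seed = 101)
co   <- generateCohort(spec)
co$batch
#> RoiTimeSeriesBatch: 200 subject(s) x 50 ROIs x 200 time points (standardized)

cfg <- dsamConfig(nRois = 50, tPoints = 200, epochs = 16, lr = 3e-3,
                  batchSize = 8, lrPatience = 5, earlyStopPatience = 7,
                  edgeMode = "constant", seed = 11)
folds <- stratifiedKfold(co$labels, 5, seed = 11)
fold  <- trainFold(co$batch, co$labels, cfg,
                   folds[[1]]$train, folds[[1]]$test)
unlist(fold$metrics[c("auc", "accuracy", "sensitivity", "specificity")])
#>         auc    accuracy sensitivity specificity
#>           1           1           1           1
```

All 40 held-out subjects are classified correctly: the network recovered
the planted connectivity difference. The same pipeline trained on shuffled
labels stays at chance (test AUC 0.50 in the acceptance run), confirming
the signal is real rather than leakage. The learned directed FC can then
be compared between groups:

```r
sub <- roiTimeSeriesBatch(batchData(co$batch)[fold$testIdx, , ])
fc  <- extractGroupFc(fold$fit, sub, co$labels[fold$testIdx])
st  <- pairwiseGroupTtests(fc$perSubject, co$labels[fold$testIdx],
                           alpha = 0.05, correction = "bonferroni")
st
#> GroupFcStats: 50 x 50 pairs, 0 significant at alpha = 0.05 (bonferroni, 2450 tests)
networkSummary(st, co$map)
#> network1 network2 network3 network4 network5 network6 network7
#>        0        0        0        0        0        0        0
```

With only 20 subjects per group in the holdout, a Bonferroni correction
over 2450 ordered pairs leaves no individually significant learned-FC
difference — the expected outcome at this sample size (full-scale studies
use holdouts an order of magnitude larger). The classifier
aggregates many weak edge differences; the t-test pipeline demands
edge-level significance. Its statistical behaviour is exercised in the
tests at adequate power: an injected unit mean shift at n = 200 per group
reproduces the closed-form t = sqrt(n/2) within 2% and survives
correction, and the null false-positive count stays at zero across 20
replicate cohorts.

`fixtureSpec()` controls the cohort (block sizes, within/between-network
correlation, AR(1) coefficient, effect edges); `dsamConfig()` exposes every
architectural and training knob, with defaults matching the reference
configuration (N = 100 ROIs, T = 1200, 150 epochs). A thin command-line
front end ships in `inst/scripts/dsam`
(`dsam fixtures make | train | eval | extract-fc`).

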