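---
title: "Predicting drug-drug interactions from fused similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interactions from fused similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddinet)
```

## The problem

Concurrent use of two drugs can modify or amplify their effects; such
drug-drug interactions (DDIs) are a leading cause of adverse events, and
experimentally screening all pairs is infeasible. The catalogue of known
DDIs is itself the strongest predictor of unknown ones: similar drugs tend
to interact with similar partners. `ddinet` operationalizes that premise as
a four-stage pipeline over an $m \times m$ binary interaction matrix $Y$
and one or more drug-similarity matrices ("views", entries in $[0,1]$),
all indexed by a shared ordered list of drug identifiers.

1. **GIP kernel.** The Gaussian Interaction Profile similarity compares
   interaction profiles (columns of $Y$):
   $G_{ij} = \exp(-\gamma_d \lVert Y_i - Y_j \rVert^2)$, with
   $\gamma_d = \tilde\gamma_d \big/ \tfrac1m \sum_i |Y_i|^2$ so the
   bandwidth adapts to the average interaction count per drug and the
   kernel scale is independent of dataset size. $\tilde\gamma_d = 1$ by
   default.
2. **Entropy/redundancy selection.** Each candidate view is scored by its
   mean row entropy $E(A) = \tfrac1m \sum_i \left( -\sum_j p_{ij} \log
   p_{ij} \right)$ with $p_{ij} = a_{ij} / \sum_k a_{ik}$. Views with
   $E > c_1 \log m$ are discarded as random-like; the survivors are
   visited in ascending entropy order, and every view with affinity
   $S(A,B) = 1/(1 + \lVert A - B \rVert_F) > c_2$ to an already selected
   view is discarded as redundant. Both thresholds default to 0.6.
3. **Similarity Network Fusion.** The selected views are merged by
   iterative KNN-based cross-diffusion: each view contributes a
   row-stochastic full kernel and a sparse kernel over its $K$ nearest
   neighbours; for $t$ iterations each full kernel is diffused through
   the average of the other views' kernels via its own sparse kernel,
   then symmetrized, diagonally regularized and row-renormalized. The
   fused matrix is the mean of the final kernels.
4. **Neural pair classifier.** The ordered pair $(i, j)$ is represented
   by row $i$ of the fused matrix concatenated with row $j$ (length
   $2m$). A feed-forward network with hidden layers of 300 and 400
   rectifier units, dropout 0.5 after each, and a sigmoid output unit is
   trained with mini-batch SGD (momentum 0.9, batch 200) on binary
   cross-entropy.

Evaluation is stratified $k$-fold cross-validation over all unordered
pairs $i<j$, optionally repeated, reporting AUC, AUPR and
precision/recall/F-measure at the F-optimal threshold.

## Leakage control

The GIP kernel is a function of the labels being predicted, so inside
cross-validation `run_cv()` zeroes the held-out pairs (both orders) in a
copy of $Y$ *before* computing GIP, running selection, fusing, or
training; the held-out labels are only consulted when scoring. The
`keep_fold_details = TRUE` switch retains, per fold, the masked entries,
the training pair list and the stage inputs so the suite can audit that
nothing leaked. A `gip_scope = "global"` switch reproduces the less
careful protocol (GIP computed once from the full matrix) for comparison;
it is not the default.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `gamma_scale` | 1 | dimensionless GIP bandwidth multiplier |
| `c1` | 0.6 | entropy cut at `c1 * log(m)` (nats) |
| `c2` | 0.6 | affinity above which a view is redundant |
| `snf_k` | 20 (capped at m-1) | fusion neighbourhood size |
| `snf_t` | 20 | fusion iterations |
| `snf_alpha` | 1 | diagonal regularizer per iteration |
| `hidden` | (300, 400) | hidden layer widths |
| `dropout` | 0.5 | per hidden layer |
| `learning_rate` | 0.01 | SGD step size |
| `momentum` | 0.9 | SGD momentum |
| `batch_size` | 200 | samples per update |
| `epochs` | 50 | passes over training pairs (20 suits large dense benchmarks) |
| `k`, `repeats` | 5, 1 | cross-validation layout |

The selection thresholds and all network hyperparameters other than the
learning rate follow the published configuration for this pipeline; the
learning rate was never published and 0.01 is the conventional
SGD-with-momentum choice, so it is exposed prominently in `nn_config()`.
The fusion constants $K = 20$, $t = 20$ and unit diagonal regularization
are the reference defaults of the fusion method.

## Numerical and design choices

**Logarithm base.** Entropies and the threshold $c_1 \log m$ use the
natural logarithm; the comparison is base-invariant as long as both sides
share a base. $0 \log 0 := 0$. The diagonal participates in row
normalization (an `exclude_diagonal` switch is provided for sensitivity
analysis). Ranking ties are broken lexicographically by view name so the
selection is deterministic.

**Ordered pairs.** The concatenation features make $(i,j)$ and $(j,i)$
different inputs while the label is symmetric. Training therefore uses
both orderings of every training pair (doubling the data and teaching the
symmetry), and evaluation scores an unordered pair as the mean of its two
directional scores. Self-pairs are excluded from training and evaluation
by default — self-interaction is not a DDI — with an `include_self`
switch. For bookkeeping against the published benchmark tables,
`count_pair_universe()` keeps the ordered $m^2$ convention those tables
use.

**Input standardization.** Fused similarity rows live on a $1/m$ scale.
The published initialization draws biases uniformly from $(-1, 0)$; with
raw features the rectifier pre-activations then sit around $-0.5 \pm
0.02$, every hidden unit is silent for every sample, and no gradient ever
reaches the hidden layers. `mlp_train()` therefore standardizes each
feature column by default (the transform is stored in the model and
applied at prediction), which restores a healthy activation spread while
keeping the published initialization. A `bias_init = "zero"` switch is
available; `standardize = FALSE` reproduces the raw behaviour.

**Tie-breaks and determinism.** KNN neighbourhoods break ties by lower
column index; fold assignment distributes each class round-robin over a
seeded random fold order (sizes and per-fold class counts within one);
every stochastic component (generator, folds, initialization, dropout,
batch order) is seeded, so a run is reproducible end to end.

**Degenerate inputs.** All-zero interaction matrices are rejected at the
GIP stage (the bandwidth would divide by zero); zero-sum similarity rows
contribute zero entropy with a warning but are fatal to the fusion kernels
(a drug with no off-diagonal similarity mass cannot be diffused); a single
surviving view skips fusion and passes through unchanged, which is also
how single-view datasets (one similarity type and no GIP) are handled.

## The synthetic benchmark

`synthetic_benchmark()` generates self-contained data with the dependence
structure the pipeline assumes, so every stage is testable without
downloads. Drugs fall into `n_clusters = 4` balanced latent clusters; a
random symmetric compatibility relation over cluster pairs (density 0.2,
at least one pair) decides where interactions concentrate:
`p_within = 0.35` between compatible clusters, `p_between = 0.02`
elsewhere. With these defaults the positive prevalence is about 7-9%,
matching the sparse regime of the public DDI benchmarks.

Informative views reflect the clusters the way real similarity matrices
do: each drug resembles a handful of same-cluster analogues, graded as
$0.9\,e^{-|u_i - u_j|/0.15}$ by per-view latent positions
$u \sim U(0,1)$, zero between clusters, with symmetric multiplicative
noise. The graded, sparse rows are essential: a view only clears the
entropy cut when its mean row entropy is below $0.6 \log m$ (2.46 nats at
$m = 60$), i.e. when the effective support of a row is below
$m^{0.6} \approx 12$ drugs. A flat dense block design (uniform
within-cluster similarity plus a dense background) has row entropy well
above that for any cluster size $\ge 12$, and would be eliminated as
random-like — dense flat similarity is exactly what the entropy filter is
built to remove, as it removes the chemical-similarity view on the real
data. Two adversarial views complete the benchmark: a near-uniform view
(off-diagonal $1/m$, entropy $\log(m-1)$, always above the cut) that the
entropy filter must remove, and a near-duplicate of the first informative
view (additive noise sd 0.001, affinity $\approx 0.93$) that the
redundancy step must remove.

What the benchmark does *not* emulate: real similarity matrices are not
conditionally independent given a single clustering, interaction
probabilities are not homogeneous within blocks, and the drug universe is
two orders of magnitude larger. Passing the recovery tests shows the
pipeline's stages compose correctly and detect planted structure; it does
not certify performance on DrugBank-scale data.

A consequence of the block-noise design worth stating plainly: given the
views, labels inside a block are independent coin flips, so the best
achievable (Bayes) score is two-valued and the attainable AUC is capped at
$\tfrac12(1 + a - b) \approx 0.84$, where $a$ and $b$ are the fractions
of positives and negatives falling in compatible blocks. The recovery
tests report the measured values against their stated bars; the
permutation control (pair labels shuffled) must and does sit at chance.

## Problem sizes

The packaged tests and the acceptance script run the full pipeline at the
generator defaults ($m = 60$, 1770 unordered pairs, five generator seeds,
five-fold cross-validation, with a matching permutation control per seed)
and smaller configurations for the stage-level tests; one full
cross-validated run takes well under a minute on a single core. Scaling
the same code to the public benchmarks ($m = 548$-$807$, $10^5$ ordered
pairs, 20 repeats) is a matter of hours, dominated by network training,
and is deliberately not part of the test surface.

## Known limitations

* Negative labels are absences of evidence; measured precision
  understates the truth when "false" positives are simply undiscovered
  interactions (several top false positives on the public data are now
  catalogued interactions).
* The fusion contract follows the canonical cross-diffusion algorithm;
  other published variants differ in normalization details and will not
  reproduce entry-for-entry.
* The nested hyperparameter search (`tune_nested_cv()`) evaluates a
  user-supplied grid with a 3-fold outer loop; the full published grid
  (5 depths x 5 widths x 3 activations x 2 dropout rates) is expensive
  and the packaged tests exercise reduced grids only.
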