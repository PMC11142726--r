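---
title: "Supervised GRN inference by graph embedding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised GRN inference by graph embedding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnlink)
```

## The problem and the model

`grnlink` casts gene regulatory network (GRN) inference from single-cell
RNA-seq as supervised link prediction: given a genes x cells expression
matrix and a partial reference network of known TF -> target edges, score
every candidate directed edge with the probability that the TF regulates the
target. The model has three stages, trained end to end by binary
cross-entropy.

**1. Node embedding.** Each gene is a node whose raw features are its
(prepared) expression profile across cells. One GraphSAGE-style layer per
hop updates node $v$ as

$$h_v \leftarrow \mathrm{ReLU}\!\left(W \cdot
  \mathrm{concat}\!\left(h_v,\; \mathrm{agg}\{h_u : u \in N(v)\}\right)\right),$$

where $N(v)$ is the neighborhood induced by the *training-fold positive
edges* and agg is the elementwise mean (default), elementwise max, or the
final state of an LSTM run over a seeded random permutation of the
neighbors. There is no bias term and no row normalization; a node with no
neighbors aggregates to the zero vector. With the default one hop, the
embedding of a gene is a function of its own profile and its direct
neighbors only.

**2. Top-k pooling.** A learnable vector $p$ scores every node by
$\mathrm{ReLU}(X p / \lVert p \rVert)$; the $k$ highest-scoring nodes
(ties to the lowest index) are kept and their embedding rows gated by
$\tanh$ of the score, keeping the selection differentiable. These $k$ rows
summarize the globally most influential genes and are shared by every
candidate edge in a forward pass. The pruned adjacency restricted to the
selected nodes is computed for completeness but consumed nowhere
downstream — only the gated node vectors enter the classifier.

**3. Pair classification.** For a candidate edge $(i, j)$ the
$(k{+}2) \times d$ matrix $[h_i; h_j; \text{pooled rows}]$ is scored by a
stack of feature-extraction blocks (BatchNorm, then a 2x2 convolution, then
ReLU, then 2x2 max pooling), whose flattened outputs are all concatenated,
passed through two fully connected layers, and squashed by a sigmoid. Row
order encodes direction, so $(i, j)$ and $(j, i)$ get different scores.
Training minimizes mean binary cross-entropy with Adam under a step-decay
schedule: learning rate $0.01 \cdot 0.8^{\lfloor \text{epoch}/10 \rfloor}$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `embed_dim` | 256 | embedding width $d$; 64–512 all run |
| `hops` | 1 | aggregation layers; each adds one neighborhood ring |
| `aggregator` | mean | mean / max / lstm neighbor summary |
| `k_pool` | 1 | pooled global-context rows in the pair matrix |
| `cnn_layers` | 3 | stacked feature-extraction blocks (1 for the ablation) |
| `kernel_size` | 2 | convolution kernel side |
| `lr0`, `lr_decay`, `lr_interval` | 0.01, 0.8, 10 | step-decay schedule |
| `epochs`, `batch_size` | 100, 256 | training length and minibatch size |
| `neg_ratio` | 1 | sampled negatives per positive |
| `n_folds` | 5 | cross-validation folds |
| `threshold` | 0.5 | score cut for confusion counts and edge categories |

## Protocol and leakage control

Positives are the reference-network edges; TF and target roles are defined
by appearance in that network. Negatives are drawn uniformly without
replacement from TF-pool x target-pool minus the positives and self-pairs,
once, and then mixed with the positives and dealt into folds (shuffle plus
round-robin, so fold sizes differ by at most one). For every fold the
aggregation graph is rebuilt from that fold's training positives only:
no test-fold edge can reach the embeddings, which the test suite asserts by
set intersection. All randomness — sampling, folds, initialization, epoch
shuffles, LSTM permutations — derives from one master seed through named
substreams, so a run is reproducible bit for bit and checkpoints round-trip
exactly.

## Design choices where the design was open

* **Neighborhood direction.** Directed TF -> target edges are symmetrized
  for aggregation (regulators see targets and vice versa), the common
  GraphSAGE convention; `directed_neighbors = TRUE` restricts a gene to its
  incoming regulators.
* **Feature preparation.** `log(1+x)` then per-gene standardization are on
  by default; they stabilize the first linear map from cells to embedding
  dimensions. Constant genes standardize to zero rather than NaN.
* **Gated versus raw pooled rows.** The pair matrix uses the tanh-gated
  rows, which keeps the node selection inside the differentiable path;
  `gate_topk = FALSE` switches to raw embedding rows.
* **Head geometry at small inputs.** With $k = 1$ the head input has 3
  rows; after the first block only 1 row remains, where a 2x2 kernel cannot
  fit. Kernel and pooling windows therefore clip to the available extent
  per axis (a 1x2 kernel in later blocks); it is an error only if the
  *first* convolution cannot fit. Channel widths grow 1 → 16 → 32 → 64, the
  first fully connected layer (width 256) infers its input size at the
  first batch, and the second produces the single logit.
* **Optimization.** Plain Adam (β = 0.9/0.999) under the step-decay
  schedule. With the aggressive 0.01 initial rate the BCE head can shoot
  into saturation in the first epochs (training losses near
  $-\log 10^{-7}$) before recovering; the optional `clip_norm` setting
  clips each minibatch gradient to a global L2 norm and removes those
  excursions, at essentially unchanged final ranking quality, so the
  default leaves it off (`Inf`). Predicted probabilities are clamped to
  $[10^{-7}, 1-10^{-7}]$ before the loss logarithm, and the loss gradient
  uses the standard fused sigmoid-plus-cross-entropy form so saturated
  predictions retain a recovery gradient.
* **Decision threshold.** AUROC/AUPRC are threshold-free; the 0.5 cut only
  feeds the confusion counts and the red/green/blue/extra edge categories.
  False positives get the label `extra` because the three-color reporting
  convention names only the other categories. The reported "sparsity" of
  an evaluated network is positives / evaluated pairs — a labeled choice,
  since no standard formula exists.
* **Metrics.** AUROC is computed as the tie-aware Mann–Whitney rank
  statistic and AUPRC as the step-wise (non-interpolated) area; both are
  verified against brute-force enumeration oracles in the test suite.

## The synthetic generator

Desk-scale validation needs data with known ground truth. The generator
plants a network: a designated TF subset receives heavy-tailed out-degrees
(power-law, exponent 2, truncated at $n-1$, rescaled to a requested mean —
mimicking regulatory hubs), targets drawn uniformly, signs ±1, weights
uniform on [0.5, 1.5]. Per cell, TF activities are i.i.d. standard normal;
each regulated gene is the signed weighted sum of its regulators'
activities plus Gaussian noise (sd 0.5 by default); unregulated non-TF
genes are pure noise; all latent values pass through a monotone
$10\,e^{x}$ map so expression is non-negative and dependence survives as
rank correlation. The canonical fixture is 100 genes, 10 TFs, mean
out-degree 5, 200 cells, noise 0.5.

This is deliberately a linear-latent simulator, not a kinetic one: it makes
regulator–target dependence detectable and analyzable (Spearman and
permutation-test oracles), but it has no dropout, no overdispersion, no
temporal dynamics, and far fewer labeled edges than the cell-type-specific
reference networks used with real data. Passing its recovery tests shows
the pipeline can learn planted dependence through the full protocol; it
says nothing quantitative about performance on real single-cell data.

## Desk-scale problem sizes and what the end-to-end numbers look like

The heavy checks run the full 5-fold protocol on the canonical fixture
with the default configuration across 5 replicate seeds, plus
label-permuted nulls across 10 seeds (the null runs train for 20 epochs,
since the calibration property — ranking no better than chance without
real labels — does not depend on training length; and 10 replicates are
needed because one permutation's AUROC has a standard error near 0.07 at
fixture size, far too coarse to resolve a band around 0.5). A fixture drawn at mean out-degree 5
yields roughly 30–95 positives (the heavy tail makes this vary widely by
seed), so each fold trains on a few dozen to ~150 labeled edges — orders
of magnitude fewer than real benchmarks. At that size the classifier
(~1.5M parameters at the defaults) reaches perfect training separation
quickly; held-out ranking hinges on the expression-correlation signal, and
edge-poor draws are markedly harder than edge-rich ones. Label-permuted
runs stay near AUROC 0.5, confirming the leakage guards.

## Known limitations

* The LSTM aggregator processes neighbors sequentially per node and is the
  slowest path; it exists for the ablation axis, not for routine use.
* Batch-normalization statistics are frozen per fitted model (standard
  train/eval semantics); scoring with a different population than the
  training distribution inherits the usual BatchNorm caveats.
* The per-fold graphs make test positives structurally "new" (their
  endpoints often have empty neighborhoods), which is the correct
  leakage-safe protocol but means sparse fixtures give the aggregation
  stage little to generalize from.
* Inputs are dense matrices in memory; the intended scale is the
  BEELINE-style 500–1000 gene setting, not whole-transcriptome graphs.
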