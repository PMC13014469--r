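---
title: "Methods: the boosting autoencoder for cell-cell interaction matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the boosting autoencoder for cell-cell interaction matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and input model

`cciboost` analyzes single-cell-resolved cell-cell interaction (CCI)
data. Its central object is the cell-cell interaction matrix (CCIM):
rows are ordered (sender, receiver) pairs of single cells, columns are
ligand-receptor features from a curated database, and entries are
interaction scores. `build_ccim()` constructs these scores as the
product of the ligand expression in the sender and the cognate receptor
expression in the receiver — the single-cell convention popularized by
NICHES-style connectomics tools. Pairs are directed ((A,B) and (B,A) are
distinct observations), self-pairs are included by default, and each
feature is a single-gene ligand paired with a single-gene receptor;
multi-subunit complexes are not modeled. The scoring kernel is the one
genuinely open design point of CCIM construction, so it is isolated in
one place and the rest of the pipeline is agnostic to it.

Two preprocessing steps precede modeling. `filter_active_features()`
keeps a feature when its fraction of nonzero scores is at least
`min_nonzero_fraction` (default 0.05) and its variance is positive; an
"active" interaction has no canonical definition, and this occupancy
criterion is deliberately explicit and configurable.
`standardize_features()` z-scores each column, by default with the
population standard deviation (`ddof = 0`); componentwise boosting
scores candidate features by inner products with the response, which is
only a fair comparison across columns of equal scale. Standardization is
idempotent and refuses constant columns by name.

## Model

For a standardized CCIM $X \in \mathbb{R}^{n \times p}$ the model has
three parts.

**Linear encoder.** $Z = X B^\top$ with $B \in \mathbb{R}^{d \times p}$
initialized at zero. There is no bias and no nonlinearity: every latent
dimension is a sparse linear combination of ligand-receptor features,
and $B$ itself is the interpretable output of training.

**Split-softmax clustering layer.** Each latent row $z$ is split into
positive and negative parts, $s = (\max(z, 0), \max(-z, 0)) \in
\mathbb{R}^{2d}$, followed by a row-wise softmax (with max-subtraction
for numerical stability). Each of the $2d$ outputs is a soft cluster;
a dimension can carry two groups of cell pairs, one per sign, and the
split gives negative activations their own clusters instead of mapping
them toward zero probability as a direct softmax would. With $d = 30$
the model exposes 60 clusters.

The cluster indexing is a fixed, documented convention: clusters
$1..d$ are the positive parts of dimensions $1..d$ and clusters
$d+1..2d$ the negative parts (`cluster_layout()` maps between the two
namings). Any consistent convention works; this one keeps block
arithmetic trivial.

**Decoder.** A feed-forward network maps the cluster probabilities $P$
(not $Z$) back to the $p$ interaction scores. The default architecture
is one hidden layer of width $2d$ with tanh and a linear output; a
single linear layer (`decoder_hidden = integer(0)`, `activation =
"linear"`) is available and is what the package's own benchmark uses
(see below). The loss is the mean squared error over all $n \cdot p$
entries — standardized inputs make squared deviation the natural
measure, and nothing in the architecture depends on this choice.

## Training

Training alternates two updates per epoch on the full batch:

1. **Boosting pass.** A single backward pass at the current parameters
   produces pseudo-responses $u_l = -\partial L / \partial z_l$, one per
   latent dimension, each mean-centered (the base learner is an
   intercept-free univariate fit). For each dimension in order, the
   response is residualized against the *current* activations of the
   other dimensions (least-squares projection with intercept, pivoted-QR
   solve, rank-deficiency safe), the feature with the largest univariate
   residual-sum-of-squares improvement
   $(x_j^\top u)^2 / (x_j^\top x_j + \varepsilon)$ is selected
   (ties to the lowest index, $\varepsilon = 10^{-12}$ guards empty
   columns), and $B[l, j^\ast]$ moves by $\nu \hat\beta_{j^\ast}$.
   Dimension $l$'s activations are recomputed before dimension $l+1$, so
   later dimensions are residualized against the update just made.
   Weights are never pruned; sparsity comes entirely from zero
   initialization plus one selection per dimension per update.
2. **Decoder pass.** `decoder_steps` plain gradient-descent steps on the
   decoder parameters against the reconstruction loss with the updated
   encoder.

Residualization is the default disentanglement mechanism; a hard
exclusion mode (`disentanglement_mode = "mask"`, features selected by
other dimensions are removed from the candidate set) is available. The
residualization route lets two dimensions share a feature when the data
genuinely call for it while still steering them toward uncorrelated
factors, which is why it is the default.

### Numerical choices that matter

- **Subgradient at zero.** The split transformation is not
  differentiable at $z = 0$, and the model *starts* at exactly $z = 0$
  everywhere. One-sided derivatives (0 for both parts) would make every
  pseudo-response identically zero and training could never leave the
  initialization. The backward pass therefore uses the symmetric
  subgradient $1/2$ for both parts at zero, which reproduces the
  one-sided derivatives' average and breaks the deadlock using the
  asymmetry of the randomly initialized decoder.
- **Pseudo-response rescaling.** The averaged MSE puts a $1/(np)$ factor
  on every gradient, so raw boosting coefficients are of order $10^{-5}$
  and the encoder would effectively never grow. Inside the training loop
  the response matrix is rescaled by one shared factor (its largest
  column root-mean-square) before the boosting pass. A single global
  factor — rather than per-column standardization — preserves the
  relative gradient magnitudes across dimensions, so dimensions whose
  signal is already captured take correspondingly small updates instead
  of having their noise amplified to unit scale. Feature selection is
  invariant to any positive rescaling; only the accumulation rate
  changes.
- **Restarts.** The alternating optimization is sensitive to the decoder
  initialization in the same way k-means is to its starting centers:
  a poor draw can lock two dimensions onto the same group of cell pairs.
  Final reconstruction loss discriminates such runs sharply, so `bae()`
  trains `n_starts` (default 5) full runs from decoder seeds derived
  deterministically from `seed` and keeps the lowest final loss.
  Training is bit-for-bit reproducible given `seed`.
- **Degenerate runs.** `epochs = 0` is valid and exact: zero encoder,
  zero latent representation, uniform cluster probabilities $1/(2d)$,
  empty loss trace.

### Defaults

| parameter | default | rationale |
|---|---|---|
| `step_size` (ν) | 0.1 | standard componentwise-boosting shrinkage; smaller values trade epochs for stability |
| `updates_per_epoch` | 1 | one selection per dimension per epoch keeps the sparsity bound interpretable |
| `epochs` | 100 | past the point where planted signatures saturate; see the overfitting note below |
| `learning_rate` | 0.5 | decoder gradients inherit the 1/(np) loss scale; at the conventional 1e-2 the decoder is effectively frozen and the joint optimization stalls |
| `decoder_steps` | 20 | lets the decoder track the encoder within an epoch without a second-order method |
| `n_starts` | 5 | restart count; diminishing returns beyond this at benchmark scale |
| `neighbors`, `min_dist` | 15, 0.1 | UMAP conventions |

One behavior worth knowing: boosting adds a weight every epoch to every
dimension, and weights are never removed. Long after a dimension's real
signal is exhausted, selection continues into noise features. These late
weights are small but accumulate variance in the latent representation,
so *more epochs are not monotonically better* once reconstruction has
plateaued — the packaged benchmark uses 50 epochs for exactly this
reason. A natural extension (not implemented) is a per-dimension
stopping rule on the selection gain.

## The planted benchmark

`simulate_ccim()` generates the package's standard test bed: $k$ groups
of cell pairs, each elevated by effect size $\mu$ on its own disjoint
block of `signature_size` features, plus i.i.d. Gaussian noise — the
post-standardization regime the model actually consumes, with
ground-truth labels and signatures. Defaults: $k = 4$ clusters of 200
pairs, $p = 40$ features, 3-feature signatures, $\mu = 3$, $\sigma = 1$.
`run_planted_benchmark()` trains one model per seed with
`benchmark_config()` — $d = 4$, 50 epochs, 2 boosting updates per
dimension per epoch, and a *linear* single-layer decoder, which proved
markedly more stable across seeds than the tanh default here and keeps
the cluster-to-centroid mapping analyzable — and scores cluster recovery
(adjusted Rand index of the hard assignments against the planted
labels), signature recovery (top-3 precision/recall after greedy
maximum-overlap matching of model clusters to planted clusters), loss
descent, and the maximum absolute pairwise correlation between latent
dimensions.

What the generator deliberately does not emulate: count noise, dropout,
library-size variation, correlated features, overlapping signatures, or
unbalanced clusters. Passing the benchmark shows that the joint
optimization recovers clean planted structure at realistic
signal-to-noise; it does not certify performance on real CCIMs, where
feature correlation and cluster imbalance are the norm. The evaluation
conventions are: empty ranked lists score zero precision and recall;
cluster matching is greedy by label overlap (optimal matching is
unnecessary at $k = 4$); a single-entry ranked list gets importance 1
(min-max normalization is undefined for one point).

## Interpretation conventions

- Hard assignments take the row argmax of $P$, ties to the lowest
  index. Softmax is monotone, so this equals the argmax over the split
  activations — a useful cheap oracle.
- Ranked lists for a cluster use only the encoder weights of the
  matching sign (strictly positive for a positive-part cluster,
  strictly negative — in absolute value — for a negative-part one), and
  min-max normalization runs over those selected weights only. A zero
  weight means "not selected" and never appears; importance 0 therefore
  means "weakest selected", which is distinct from "not selected".
- Embeddings default to UMAP on the latent representation $Z$ (the
  cluster probabilities work too), seed fixed, with shape, finiteness,
  row order, and seeded reproducibility as the only contract.

## Known limitations

- Full-batch training only; CCIMs at desk scale fit in memory, and the
  boosting pass is not formulated for minibatches here.
- The scoring kernel is the NICHES-style product; alternative kernels
  plug into `build_ccim()` but none ship.
- No statistical testing of interactions — by design, selection replaces
  post-hoc testing, but that also means no p-values.
- Spatial coordinates are carried as metadata only.
- The softmax temperature is fixed at 1; the config field is reserved.
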