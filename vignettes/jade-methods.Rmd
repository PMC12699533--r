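---
title: "Joint alignment and embedding of SRT slice pairs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint alignment and embedding of SRT slice pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jade)
```

## The problem

Two adjacent (or replicate) tissue sections measured with a spatial
transcriptomics platform share biology but not geometry: sectioning and
mounting deform the tissue, capture efficiency drifts, and per-gene batch
effects shift the expression scale. Joint analysis needs (a) a spot-level
correspondence between the sections and (b) a shared low-dimensional
representation in which the sections are comparable. These two estimates
inform each other, which is why this package fits them together rather than
sequentially.

## Model

For slices $(S_1, X_1)$ and $(S_2, X_2)$ over a common gene panel of size
$p$:

**Spatial graph.** A symmetric $k$-nearest-neighbour graph on the
coordinates (default $k = 6$, the hexagonal neighbour count of spot-array
platforms), degree-normalized as $\tilde A = D^{-1/2} A D^{-1/2}$. Self
loops are added by default before normalization; without them an isolated
spot would be annihilated by the convolution (the literal no-self-loop
formula is available via `normalize_adjacency(..., add_self_loops =
FALSE)`).

**Autoencoder.** One-layer GCN encoder $H = \mathrm{ReLU}(\tilde A X W^e +
b^e)$ and decoder $\hat X = \mathrm{ReLU}(\tilde A H W^d + b^d)$, with
reconstruction loss $\frac{1}{n_1}\lVert X_1-\hat X_1\rVert_F^2 +
\frac{1}{n_2}\lVert X_2-\hat X_2\rVert_F^2$. Because the decoder output is
nonnegative, preprocessing defaults to log-normalized values *without*
unit-variance scaling (the `scale_unit_variance` flag exists but interacts
poorly with ReLU reconstruction).

**Contrastive refinement.** A graph-infomax objective: each spot's
embedding $h_i$ is paired with its neighbourhood mean $r_i$ (positives)
and with row-shuffled embeddings and their proxies (negatives); a bilinear
discriminator $\sigma(h^\top \Phi r)$ is trained with binary cross-entropy,
averaged per spot and summed over the two slices. A zero discriminator
sits exactly at the chance level $2\log 2$ per slice, a useful analytic
anchor that the tests pin down.

**Alignment.** Embeddings are projected by a learned $M$ and compared
bilinearly; the row-softmax of the scaled scores is balanced by
Sinkhorn–Knopp to the transport polytope with uniform marginals $1/n_1$,
$1/n_2$. Three losses act on the plan $\Pi$: a Gromov-style structure
term comparing $D_1$ with $n_2^2\,\Pi D_2 \Pi^\top$ (and symmetrically with
$n_1^2$), an alignment term comparing $H_1$ with $n_2\,\Pi H_2$ (and
symmetrically), and a KL penalty of the column sums against uniform.

**Total objective and weights.** $L = L_{SCL} + \lambda_2 L_{recon} +
\lambda_3 L_{maintain} + \lambda_4 L_{align} + \lambda_5 L_{marginal}$ with
$\lambda_2 = 10$, $\lambda_4 = 0.1$, $\lambda_5 = 1$. $\lambda_3$ is
selected in $[0.2, 2.0]$ from data: similar slices should share more
spatial structure. The selector is the Pearson correlation $\rho$ of the
two pseudo-bulk (gene-wise mean) profiles mapped as $\lambda_3 = 0.2 + 1.8
\max(\rho, 0)$ — monotone, bounded, and free of tuning; it is isolated in
`select_lambda3()` so any other similarity score can be swapped in.

## Design choices in the open corners

**Sign of the attention logits.** With a projection $M$, the bilinear
score $h_1^\top M M^\top h_2$ is a positive-semidefinite form. If the
balanced plan is built from $\mathrm{softmax}(-\,\cdot\,)$, then whenever
the two slices occupy a common latent region the Cauchy–Schwarz inequality
makes matched pairs score *highest* and therefore receive the *least*
mass — the plan provably concentrates on mismatches (we measure domain
accuracy 0.03 on the easy synthetic preset, i.e. systematic
anti-matching). The package therefore uses the affinity orientation by
default: since Sinkhorn normalization is invariant to per-row and
per-column factors $\exp(-\lVert M^\top h\rVert^2/d)$, the balanced plan
under $\mathrm{softmax}(+(H_1M)(H_2M)^\top/d)$ is exactly the entropic
optimal transport plan for the squared Euclidean cost in the projected
space, which is what "mass flows to corresponding spots" means. The
negative orientation remains available (`attn_sign = "cost"`) for
comparison. Logits are scaled by $d$ (not $\sqrt d$) by default; a
`sqrt_d` flag exists.

**Shared vs per-slice encoders.** With fully independent encoders the two
latent clouds are only coupled through $\lambda_4 L_{align}$, whose
gradient (an unsquared Frobenius norm scaled by $1/n$, weighted 0.1) is
orders of magnitude below the reconstruction gradient; in our experiments
the clouds never merge (iLISI stays at 1.0 out to 1500 epochs and across
learning rates, in both the phase-split and joint backprop modes) even
though alignment accuracy is high. Sharing the encoder across slices —
standard practice in multi-slice SRT representation learning — places both
slices in one latent space from the start and yields mixed embeddings
(iLISI ≈ 1.7 on the easy preset) without hurting accuracy. The default is
`share_encoder = TRUE`; per-slice encoders (and optionally a shared
decoder, `share_decoder`) are flags. Decoders stay per-slice by default so
each slice can absorb its own batch scale.

**Roundtrip realization.** Per epoch, phase E updates
encoder/decoder/discriminator on $L_{SCL} + \lambda_2 L_{recon} +
\lambda_4 L_{align}$ with the plan fixed; phase A recomputes the attention
map and truncated Sinkhorn plan and updates $M$ on $\lambda_3 L_{maintain}
+ \lambda_4 L_{align} + \lambda_5 L_{marginal}$ with embeddings fixed.
This keeps each phase's gradients on its own parameters. A joint mode
(`roundtrip = "joint"`) backpropagates the full objective — including the
paths through the softmax and the Sinkhorn recursion — into every
parameter at once; on the synthetic presets it reaches the same metrics.

**Sinkhorn.** During training the plan uses a fixed small iteration count
(default 5) so the computation stays smooth and cheap; the marginal KL
penalty exists precisely to compensate the truncation. Each iteration
ends with the row scaling, so row sums are exact and the column deviation
is what the penalty and the reported `marginal_err` measure. At inference
the plan is iterated to `tol = 1e-6` (cap 200). Entries are floored at
1e-30 before division. Gradients flow through the recursion by
reverse-mode accumulation over the stored scaling steps; all gradients in
the engine (GCN, discriminator, attention, Sinkhorn) are verified against
central finite differences in the test suite.

**Optimization.** Adam (lr $10^{-3}$, $\beta = (0.9, 0.999)$), full batch,
default 500 epochs with early stop after 50 epochs without improvement.
Weights are Glorot-uniform, biases zero, $M$ starts at identity plus small
noise so the initial cost is a meaningful bilinear form. One run seed
drives initialization, the per-epoch negative shufflings and any k-means;
runs are bitwise reproducible.

**Fast mode.** The quadratic bottleneck is the $n_1 \times n_2$ attention
map. `fast = TRUE` groups each slice's spots by k-means on coordinates
into ~10–20 % as many hyperspots, averages embeddings per hyperspot (the
averaging is differentiated through, so encoder gradients still flow),
runs attention/Sinkhorn and the three alignment-side losses at coarse
resolution, and recovers the full-resolution plan afterwards from the
trained projection. `hyperspot_fraction = 1` uses an identity partition
that executes the identical code path as the full model — bitwise equal
results, which the tests assert. Contrastive and reconstruction losses
stay at full resolution: they are linear in $n$ and are not the
bottleneck.

## Downstream utilities

Embeddings are L2-normalized per spot and clustered with a shared-
covariance Gaussian mixture (`mclust`, model EEE), falling back to an
EEE/EII fit under a conjugate prior and finally to k-means if the
covariance degenerates (unit-normalized clouds often have low intrinsic
dimension). ARI is the standard permutation-model index. iLISI uses
perplexity-weighted Gaussian neighbourhoods (perplexity 30) over the joint
embeddings; for two slices it lives in $[1, 2]$. Alignment accuracy takes
each slice-1 spot's argmax match and asks whether the domain labels agree;
spots whose maximal mass falls below `unaligned_threshold`$/(n_1 n_2)$
count as incorrect by default (an `exclude` mode drops them instead — the
choice matters only for very diffuse plans). Domain markers use
one-vs-rest Wilcoxon rank-sum tests with Benjamini–Hochberg correction
within each domain, ranked by difference of means.

## The synthetic generator

`generate_paired_slices()` emulates an adjacent-section pair: slice 1 on a
jittered grid in the unit square with layered (or blob/ring) domains;
per-domain expression programs are a log-normal baseline with
`signal_strength` log-fold marker elevation on ~15 % of genes per domain;
counts are negative-binomial (`noise` = dispersion) with optional dropout.
Slice 2 carries a `match_fraction` subsample of slice-1 spots through a
rotation plus smooth sinusoidal warp, re-draws counts from the same
programs with per-gene log-normal batch factors applied to the means (so
counts stay integral), and records the ground-truth correspondence.

The *easy* preset (300 spots, 200 genes, 4 layers, signal 1.5, dispersion
0.25, batch SD 0.15, dropout 0.05, rotation 0.05 rad, warp 0.03) is
calibrated so that a naive nearest-centroid classifier already recovers
domains (ARI > 0.9) — it tests the machinery, not the statistical limit.
The *hard* preset (signal 0.6, dispersion 1.0, batch SD 0.5, dropout 0.3,
partial overlap 0.8) exists for robustness work. What the generator does
**not** emulate: platform-specific artifacts (tissue tears, fiducials),
spatially varying capture efficiency, within-domain expression gradients,
and realistic gene–gene correlation; passing on synthetic data therefore
demonstrates correctness of the estimator, not performance on real tissue.

## Problem sizes and numerical conventions

The test suite and the acceptance script train 300-epoch models on
300-spot pairs with 200 genes and latent dimension 32 (< 1 minute each on
one CPU core); unit tests use 5–80 spots. Degenerate inputs are handled
explicitly: zero-norm residuals get zero gradient; empty k-means clusters
are repaired by splitting the largest; constant genes get p-value 1 in the
marker test; zero-variance pseudo-bulk profiles fall back to
$\lambda_3 = 0.2$ with a warning. Coordinates are treated as unitless
continuous 2-D positions; squared-distance matrices are divided by their
mean off-diagonal entry by default so the maintenance loss is
platform-independent (raw distances via `mean_normalize = FALSE`).
Distance ties in the kNN graph break toward the lower spot index.

## Known limitations

* Pairwise only: more than two slices require repeated pairwise runs.
* The full-resolution attention map is dense ($n_1 n_2$ memory); beyond
  ~10⁴ spots per slice use `fast = TRUE`.
* The data-driven $\lambda_3$ selector is a simple pseudo-bulk
  correlation; heterogeneous compositions between slices can inflate it.
* h5ad input/output relies on an external `python` with `anndata`.
* The model assumes a shared gene panel and a common expression scale
  after log-normalization; strong platform differences (e.g. probe-based
  vs full transcriptome) are not modelled beyond the per-gene batch term.
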