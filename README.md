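# jade

Joint alignment and deep embedding of paired spatially resolved
transcriptomics (SRT) slices.

When two adjacent or replicate tissue sections are profiled with a spatial
platform (10x Visium, Stereo-seq, MERFISH, ...), two questions have to be
answered together: *which spot corresponds to which* across the sections
(alignment), and *what shared low-dimensional representation* describes both
sections despite deformation and batch effects (embedding). Most tools
answer one question at a time; `jade` answers both jointly, for analysts who
want a probabilistic spot-level correspondence **and** batch-mixed
embeddings for downstream domain detection from a single model fit.

## The model

Given slices `(S1, X1)` and `(S2, X2)` with coordinates `S_i` and expression
`X_i` over a shared gene panel, `jade` learns

* per-slice one-layer GCN autoencoders
  `H_i = ReLU(Ã_i X_i W^e + b^e)`, `X̂_i = ReLU(Ã_i H_i W_i^d + b_i^d)`,
  where `Ã = D^{-1/2} A D^{-1/2}` is the degree-normalized k-NN spatial
  graph (the encoder is shared across slices by default, so both slices
  live in one latent space);
* a cross-attention transport plan: logits `(H1 M)(H2 M)^T / d` with a
  learned projection `M`, row-softmaxed and balanced by Sinkhorn–Knopp to
  uniform marginals `1/n1`, `1/n2`. Because Sinkhorn is invariant to row and
  column scalings, the balanced plan is exactly entropic optimal transport
  under the squared Euclidean cost of the projected embeddings;
* the objective
  `L = L_SCL + λ2 L_recon + λ3 L_maintain + λ4 L_align + λ5 L_marginal`
  with `λ2 = 10, λ4 = 0.1, λ5 = 1` and `λ3 ∈ [0.2, 2]` selected from the
  slices' pseudo-bulk correlation. `L_SCL` is a graph-infomax contrastive
  loss (bilinear discriminator, row-shuffled negatives), `L_maintain`
  compares `D1` with `n2² Π D2 Πᵀ` (and symmetrically), `L_align` compares
  `H1` with `n2 Π H2` (and symmetrically), and `L_marginal` is the KL of the
  plan's column sums to uniform, compensating the truncated (5-iteration)
  Sinkhorn used while training.

Training alternates per epoch between refining the networks with the plan
fixed and refining `M` through the plan (the roundtrip scheme); everything
is optimized with Adam under a single run seed, so runs are bitwise
reproducible. For large slices, *Fast-JADE* (`fast = TRUE`) coarsens the
quadratic attention/transport step onto k-means "hyperspots" (10–20 % of
spots) and recovers the full-resolution plan afterwards with the trained
projection.

## Worked example

```r
library(jade)

sim <- generate_paired_slices(synthetic_preset("easy", seed = 0))
pp  <- preprocess_pair(sim$slice1, sim$slice2, preprocess_config(n_hvg = 200))
fit <- train_jade(pp[[1]], pp[[2]], config = jade_config(epochs = 300, seed = 0))
fit
#> jade_result: 300 x 300 plan (marginal_err 9.53e-07), d = 32, 300 epochs, final total loss 2318.7710

alignment_accuracy(fit$plan, pp[[1]]$labels, pp[[2]]$labels)$accuracy
#> [1] 0.9766667
cl <- cluster_embeddings(fit$embeddings$h1, k = 4, seed = 0)
adjusted_rand_index(cl$labels, pp[[1]]$labels)
#> [1] 0.9386376
ilisi_score(rbind(fit$embeddings$h1, fit$embeddings$h2),
            rep(c("s1", "s2"), each = 300))
#> [1] 1.697779
```

The three numbers answer the three questions: 97.7 % of spots map (by the
plan's row argmax) to a spot of their own ground-truth domain; clustering
the embeddings recovers the four planted domains at ARI 0.94; and the two
slices are well mixed in the joint latent space (iLISI 1.70 on a 1–2 scale
where 1 is fully separated and 2 perfectly mixed).

The same pipeline is available from the shell:

```sh
exec/jade simulate --preset easy --n 300 --seed 0 --outdir runs
exec/jade run --slice1 runs/<sim>/slice1 --slice2 runs/<sim>/slice2 \
              --outdir runs --epochs 300 --seed 0
exec/jade eval --result runs/<run> --truth1 runs/<sim>/slice1/labels.tsv \
               --truth2 runs/<sim>/slice2/labels.tsv
```

Every result directory carries a `manifest.json` (config, seed, input and
output checksums) and is reproducible from it.

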