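---
title: "Methods: mosaic multimodal integration with a product-of-experts VAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic multimodal integration with a product-of-experts VAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell experiments increasingly measure several molecular layers —
transcriptome (RNA), chromatin accessibility (ATAC), surface proteins
(ADT) — but rarely all of them in every experiment. A *mosaic* collection
is a set of batches that each carry a different subset of modalities:
batch A might have RNA+ATAC, batch B RNA+ADT. Integrating such data means
placing every cell into one shared low-dimensional embedding in which
cells of the same type sit together regardless of which batch they came
from and which modalities they carry, while technical batch differences
are removed.

`scmosaic` implements a modular variational autoencoder for this setting.
Each modality has its own Gaussian encoder and decoder; a cell's
available modalities are fused into a single posterior by a product of
experts; and the latent space is additionally shaped by three structure
terms: a graph cross-entropy that preserves each modality's
mutual-nearest-neighbor topology, an InfoNCE contrastive term on
neighbor-derived positive pairs, and a triplet margin term that exploits
partial cell-type labels.

## Model

For cell $n$ with observed modalities $\mathcal{M}_n$, each encoder
produces a diagonal Gaussian $q_\phi(z \mid x_n^m) =
\mathcal{N}(\mu_n^m, \mathrm{diag}(\nu_n^m))$. Multiplying these expert
densities with the standard-normal prior gives another diagonal Gaussian
with

$$\nu_n = \Big(1 + \sum_{m \in \mathcal{M}_n} 1/\nu_n^m\Big)^{-1},
\qquad
\mu_n = \Big(\sum_{m \in \mathcal{M}_n} \mu_n^m/\nu_n^m\Big) \circ \nu_n ,$$

i.e. precisions add (the leading 1 is the unit-variance prior expert) and
means combine precision-weighted. With no experts the fusion returns the
prior itself. We treat $\nu$ as a *variance* throughout: the
precision-sum form is only coherent under that reading. The fused
posterior is sampled by the reparameterization trick
($z = \mu + \sqrt{\nu} \circ \varepsilon$) during training; the final
embedding is the fused *mean*, the standard convention for downstream
clustering.

Latent samples are decoded back into every available modality and scored
by summed squared error (an MSE reconstruction, not a count likelihood —
so decoders need no link function and preprocessing choices carry the
distributional burden). The KL term is the diagonal-Gaussian closed form
$\tfrac12 \sum_d (\nu_d + \mu_d^2 - 1 - \log \nu_d)$.

### Structure terms

*Graph cross-entropy.* Per modality we build a cosine mutual-$k$NN graph
on the preprocessed view over the cells where that modality is available
(an edge requires each cell in the other's top-$k$; ties break toward the
lower cell index for determinism; masked cells get empty rows). With
$A^r = \mathrm{sigmoid}(Z Z^\top)$, the loss is
$-\frac1N \sum_m \sum_{ij} A^m_{ij} \log A^r_{ij}$: only observed edges
contribute, there is no explicit negative term. $\log \mathrm{sigmoid}$
is evaluated in a shifted form that stays finite for inner products of
magnitude $10^4$ and beyond.

*InfoNCE.* Positive pairs are edges sampled from the same graphs. Each
pair is scored against the other pair members with temperature-scaled
cosine similarity; the denominator includes both "other positives seen
from the anchor" and "all anchors seen from the positive" exactly as the
definition prescribes (including the pair's own score in the second sum).
The per-modality loss averages both orientations over the $T$ pairs and
modalities are summed.

*Triplet margin.* From labeled cells we draw anchor/positive/negative
triplets (same/same/different type) and penalize
$\max(d(a,p) - d(a,n) + m, 0)$ with Euclidean $d$. The definition we
implement is the *positive* mean hinge: the printed form of this loss
sometimes appears with a leading minus sign, but minimizing a negated
hinge is unbounded below and contradicts its stated purpose (pulling
same-type cells together), so the positive orientation is the only
coherent one. Because labels are pooled across batches, triplet positives
are the one supervision signal that explicitly spans batches — it is the
main engine of batch alignment.

## Balancing the objective

The total objective is
$\lambda_1 L_{recon} + \lambda_2 L_{KL} + \lambda_3 L_{graph} +
\lambda_4 L_{con} + \lambda_5 L_{tri}$.
The five terms live on incompatible scales: reconstruction and KL are
*extensive* (sums over all cells and features, $\sim 10^5$ at even 600
cells), while the contrastive and triplet terms are means over sampled
pairs ($\sim 1$) and the graph term carries an explicit $1/N$. With
literal unit weights the three structure terms contribute under $10^{-4}$
of the objective and the model silently degenerates to a plain PoE-VAE
that cannot remove batch effects. `scmosaic` therefore interprets
$\lambda_3, \lambda_4, \lambda_5$ as *per-cell* weights and multiplies
them by $N$ at training time (`loss_weights(extensive = TRUE)`), putting
all five terms on the same extensive scale. Defaults are
$\lambda = (1, 1, 1, 1, 5)$ per cell: the proper ELBO ratio between
reconstruction and KL, unit weight for the two unsupervised structure
terms, and a stronger voice for the scarce supervised term (only ~20% of
cells are labeled in the intended regime, and it is the only
batch-bridging term).

Two related scale choices: the KL weight of 1 keeps the embedding near
the standard-normal prior, so distances in latent space have an
interpretable unit scale; and the triplet margin defaults to $m = 5$,
commensurate with between-type distances under that prior — a margin
much smaller than typical type separation is satisfied without actually
merging a type's per-batch sub-clusters and does no work.

Temperature stays at $\tau = 0.5$, $T = H = 50$ pairs/triplets per
mini-batch, $k = 15$ neighbors.

## Training

Adam (learning rate $10^{-3}$), mini-batches of 128 shuffled cells, 200
epochs by default. Graphs are built once on the full preprocessed views;
within a mini-batch the graph term uses the induced subgraph (edges
leaving the batch are picked up whenever both endpoints co-occur), and
positive pairs and triplets are resampled fresh every mini-batch from the
induced edges and the batch's labeled cells — a finer-grained version of
per-epoch resampling. Mini-batch reconstruction, KL, and graph terms are
rescaled by $N/|B|$ so the weights keep their full-data meaning. If
fewer than two labeled classes exist, the triplet weight is forced to
zero with a warning. All gradients are exact analytic expressions
(verified against central finite differences in the test suite), and a
single integer seed fixes initialization, shuffling, sampling, and
reparameterization noise, so runs are bitwise reproducible
single-threaded. Divergence (a non-finite term) aborts with the epoch
and the offending term named.

## Synthetic mosaic data

`simulate_mosaic()` generates the regime the method targets, with full
ground truth. Cell identity lives in a 10-dimensional latent space: type
centroids drawn with SD 3 per coordinate, per-cell scatter SD 1
(`noise_scale`), so types are well separated but not trivially so.
Batch effects are a shared latent offset per batch with SD
`batch_effect_scale` (default 1) plus a small per-modality feature-space
offset — smaller than type separation and shared across modalities, hence
removable in principle by a shared-latent method. Latent positions map to
each modality through a fixed random linear map and a per-cell softmax to
library-size-scaled rates; RNA/ADT counts are negative binomial
(dispersions 10/20), ATAC is Bernoulli-thinned Poisson to mimic
near-binary sparsity. The default study: 600 cells, 4 types, 2 batches,
pattern `{b0: RNA+ATAC, b1: RNA+ADT}` (RNA as bridge), 20% stratified
labels.

What the generator does *not* emulate: realistic library-size variation,
zero-inflation structure, nonlinear latent-to-feature maps,
type-specific dispersion, doublets, or empty droplets. Passing tests
show the machinery is correct and that the method removes the kind of
batch effect it models; they do not certify performance on real data.

## Preprocessing

The encoders and the graphs both consume normalized views: library-size
normalization to 10^4 followed by `log1p` for RNA and ADT, TF-IDF (then
`log1p`) for ATAC. A centered log-ratio option exists for ADT
(`methods = c(adt = "clr")`) but is not the default — the cosine graphs
are scale-sensitive and the default keeps all views on a comparable
log scale. Cells lacking a modality have `NA` rows in that view, never
silent zeros. All-zero available cells are left as zeros with a warning
(they are rejected later by graph construction, which cannot place a
zero vector on the cosine sphere).

## Evaluation

`evaluate_embedding()` reports the standard integration benchmarks:
Leiden clusters (igraph, modularity objective, resolution 1, exact
Euclidean $k$NN graph) scored against types by NMI (arithmetic-mean
entropy normalization) and ARI; graph connectivity (mean over types of
the largest-connected-component fraction of the type's induced $k$NN
subgraph); and graph iLISI/cLISI — perplexity-30 Gaussian-kernel inverse
Simpson indices rescaled to $[0,1]$ by $(s-1)/(B-1)$ for batch mixing
and $(T-s)/(T-1)$ for type purity. Note that modularity at resolution 1
deliberately over-clusters small, well-separated groups (a 100-cell blob
usually splits); resolution should be matched to the granularity of
interest when cluster *counts* matter.

The test suite's end-to-end checks run the default study at seeds 1–3:
Leiden ARI against true types reaches at least 0.8 in at least two of
the three seeds, the embedding's iLISI beats a concatenated-PCA baseline
of equal dimensionality, training is bitwise reproducible, and removing
the triplet term never helps. Problem sizes throughout the suite (600
cells for end-to-end runs, tens of cells for unit fixtures) were chosen
so the whole suite completes in a few minutes on a laptop.

## Numerical choices and limitations

- Variance link: softplus plus a floor of $10^{-6}$, protecting the
  $1/\nu$ precisions in the fusion.
- The InfoNCE softmax subtracts a global maximum before
  exponentiation; the shift cancels exactly in the gradient.
- Ties in the top-$k$ and in nearest-neighbor searches break toward the
  lower index; all samplers are seeded — the package has no
  non-deterministic code path on a single thread.
- Exact brute-force neighbor search and dense matrix algebra bound the
  practical scale to a few thousand cells; there is no approximate-NN
  index, no GPU path, no count-likelihood decoders, and no early
  stopping.
- Triplets are sampled globally, not within batch: cross-batch positives
  are what drive alignment, at the cost of assuming labels are
  comparable across batches.
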