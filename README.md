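# scmosaic

Integration of **mosaic single-cell multimodal data** — collections in
which different batches carry different subsets of modalities (RNA
transcript counts, ATAC chromatin accessibility, ADT surface proteins) —
into a single batch-corrected latent embedding, for anyone who needs to
co-embed, cluster, and annotate cells across such batches without paired
measurements everywhere.

## The method

Each modality $m$ has its own Gaussian encoder producing a per-cell
diagonal posterior $q_\phi(z \mid x_n^m) = \mathcal{N}(\mu_n^m,
\mathrm{diag}(\nu_n^m))$. A cell's available modalities
$\mathcal{M}_n$ are fused by a **product of experts** with the
standard-normal prior:

$$
\nu_n = \Big(1 + \sum_{m\in\mathcal{M}_n} 1/\nu_n^m\Big)^{-1},
\qquad
\mu_n = \Big(\sum_{m\in\mathcal{M}_n} \mu_n^m/\nu_n^m\Big)\circ\nu_n .
$$

Precisions add, means combine precision-weighted; with no experts the
fusion is the prior. Reparameterized samples are decoded per modality
and trained with five weighted terms:

$$
\mathcal{L} = \lambda_1 \mathcal{L}_{recon}
            + \lambda_2 \mathcal{L}_{KL}
            + \lambda_3 \mathcal{L}_{graph}
            + \lambda_4 \mathcal{L}_{con}
            + \lambda_5 \mathcal{L}_{tri}
$$

- $\mathcal{L}_{recon}$: summed squared reconstruction error over cells
  and available modalities;
- $\mathcal{L}_{KL}$: closed-form KL from the fused posterior to
  $\mathcal{N}(0, I)$;
- $\mathcal{L}_{graph} = -\frac1N\sum_m\sum_{ij} A^m_{ij}\log
  \mathrm{sigmoid}(z_i^\top z_j)$: the latent space must reproduce each
  modality's cosine **mutual-kNN adjacency** $A^m$;
- $\mathcal{L}_{con}$: symmetrized **InfoNCE** over $T$ positive pairs
  per modality sampled from those graph edges (temperature $\tau$,
  cosine similarity);
- $\mathcal{L}_{tri}$: mean triplet hinge
  $\max(d(a,p)-d(a,n)+m,\,0)$ over anchor/positive/negative triples
  drawn from the partially labeled cells — the only term whose positives
  explicitly span batches.

The final embedding is the fused posterior mean. Everything is seeded
and bitwise reproducible single-threaded; gradients are exact analytic
expressions checked against finite differences in the test suite. See
`vignettes/mosaic-integration-methods.Rmd` for assumptions, parameter
defaults (and why the structure weights are per-cell), and limitations.

## Worked example

Simulate the default mosaic study — 600 cells, 4 types, 2 batches where
batch `b0` assays RNA+ATAC and `b1` assays RNA+ADT (RNA as bridge),
batch-effect scale 1, 20% of cells labeled — then train and benchmark:

```r
library(scmosaic)

sim <- simulate_mosaic(simulation_config(seed = 1))
ds  <- make_semisupervised(sim$dataset, fraction = 0.2, seed = 1)
ds
#> MosaicDataset: 600 cells, 3 modalities
#>   rna       300 features,   600 cells available
#>   atac      600 features,   300 cells available
#>   adt        30 features,   300 cells available
#>   batches: b0, b1
#>   labels: 120/600 cells labeled

pre <- preprocess(ds)                       # lognorm RNA/ADT, TF-IDF ATAC
fit <- train(pre, ds, train_config(seed = 1))   # 200 epochs, ~30 s

evaluate_embedding(fit$embedding, sim$dataset$labels, ds$batch, seed = 1)
#> EvalReport:
#>   nmi                0.9412
#>   ari                0.9127
#>   graph_connectivity 1.0000
#>   ilisi              0.3019
#>   clisi              0.9979
#>   n_clusters         5
```

Leiden clusters of the embedding recover the four simulated types
nearly perfectly (ARI 0.91, NMI 0.94), every type forms one connected
neighborhood (graph connectivity 1.0) and neighborhoods are type-pure
(cLISI ≈ 1). iLISI 0.30 says batches are locally mixed; the
no-integration baseline (`pca_baseline(pre, 20)`) scores iLISI ≈ 1e-5
and ARI 0.60 on the same data because each type splits into two batch
clusters.

Real data comes in through `load_mosaic()` (MTX directories with
barcode/feature sidecars, or dense CSV; alignment by barcode union) and
out through `write_mosaic()`. A thin command-line wrapper with
`simulate` / `train` / `embed` / `evaluate` subcommands is installed at
`system.file("cli", "scmosaic.R", package = "scmosaic")`.

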