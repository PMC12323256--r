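# Shared fixtures. Training runs under the default study conditions are
# cached per seed so several test files can reuse them without retraining.

tiny_dataset <- function(seed = 11, n_cells = 60, n_types = 3) {
  sim <- simulate_mosaic(simulation_config(
    n_cells = n_cells, n_types = n_types, n_batches = 2, latent_dim_true = 5,
    n_features = c(rna = 40, atac = 60, adt = 10),
    mosaic_pattern = list(b0 = c("rna", "atac"), b1 = c("rna", "adt")),
    seed = seed))
  sim
}

.study_cache <- new.env(parent = emptyenv())

# One full run under the default study conditions: 600 cells, 4 types,
# 2 batches, mosaic pattern {b0: RNA+ATAC, b1: RNA+ADT}, batch effect 1.0,
# 20% labels, 200 epochs with default hyperparameters.
study_run <- function(seed, triplet_weight = NULL) {
  key <- paste0("s", seed, "_t", triplet_weight %||% "default")
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  sim <- simulate_mosaic(simulation_config(seed = seed))
  ds <- make_semisupervised(sim$dataset, 0.2, seed = seed)
  pre <- preprocess(ds)
  w <- if (is.null(triplet_weight)) loss_weights()
       else loss_weights(triplet = triplet_weight)
  fit <- suppressWarnings(
    train(pre, ds, train_config(seed = seed, weights = w)))
  res <- list(sim = sim, ds = ds, pre = pre, fit = fit)
  .study_cache[[key]] <- res
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
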