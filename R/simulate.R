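#' Configuration for the mosaic data simulator
#'
#' Defaults describe a desk-scale mosaic study: 600 cells of 4 types across
#' 2 batches, where batch `b0` assays RNA+ATAC and batch `b1` assays
#' RNA+ADT, so RNA is the shared bridge modality. Cell identity lives in a
#' `latent_dim_true`-dimensional space: type centroids are drawn with
#' standard deviation 3 per coordinate, cells scatter around their centroid
#' with standard deviation `noise_scale`, and each batch adds a shared
#' latent offset vector with standard deviation `batch_effect_scale` (plus a
#' small per-modality feature-space offset), so batch effects are real but
#' smaller than type separation — the regime a shared-latent method is meant
#' to remove.
#'
#' @param n_cells,n_types,n_batches Problem size.
#' @param latent_dim_true Dimension of the generative latent space.
#' @param n_features Named integer vector of per-modality feature counts.
#' @param batch_effect_scale Standard deviation of the per-batch latent
#'   offset (0 = no batch effect).
#' @param noise_scale Standard deviation of per-cell latent scatter around
#'   the type centroid.
#' @param mosaic_pattern List mapping batch name to the character vector of
#'   modalities that batch assays; the union defines the dataset modalities.
#' @param dispersion Named negative-binomial size parameter per modality
#'   (ignored for `"atac"`).
#' @param library_size Named expected total counts per cell per modality.
#' @param seed Integer; fixes all randomness.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_cells = 600, n_types = 4, n_batches = 2,
                              latent_dim_true = 10,
                              n_features = c(rna = 300, atac = 600, adt = 30),
                              batch_effect_scale = 1.0, noise_scale = 1.0,
                              mosaic_pattern = list(b0 = c("rna", "atac"),
                                                    b1 = c("rna", "adt")),
                              dispersion = c(rna = 10, atac = 10, adt = 20),
                              library_size = c(rna = 2000, atac = 4000, adt = 1000),
                              seed = 1L) {
  stopifnot(n_types >= 1, n_cells >= 1, n_batches >= 1,
            batch_effect_scale >= 0, noise_scale >= 0,
            length(mosaic_pattern) == n_batches)
  if (any(!vapply(mosaic_pattern, length, 1L)))
    stop("every batch's modality set must be non-empty")
  modalities <- unique(unlist(mosaic_pattern))
  if (!all(modalities %in% names(n_features)))
    stop("mosaic_pattern names modalities without a feature count")
  structure(list(
    n_cells = n_cells, n_types = n_types, n_batches = n_batches,
    latent_dim_true = latent_dim_true, n_features = n_features,
    batch_effect_scale = batch_effect_scale, noise_scale = noise_scale,
    mosaic_pattern = mosaic_pattern, dispersion = dispersion,
    library_size = library_size, modalities = modalities,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Simulate a mosaic multimodal dataset with known ground truth
#'
#' Draws type centroids in a true latent space, scatters cells around them,
#' adds per-batch latent offsets scaled by `batch_effect_scale`, maps the
#' latent positions to each modality through a fixed random linear map, and
#' emits negative-binomial counts for RNA/ADT and Bernoulli-thinned Poisson
#' counts (near-binary, sparse) for ATAC. The mosaic availability mask
#' follows `config$mosaic_pattern`. All cells carry their true type label;
#' use [make_semisupervised()] to hide a fraction.
#'
#' @param config A [simulation_config()].
#' @return List with `dataset` (a [mosaic_dataset()]), `latent` (the
#'   cell x `latent_dim_true` ground-truth latent matrix, batch offsets
#'   excluded), and `config`.
#' @export
simulate_mosaic <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_cells
  d <- config$latent_dim_true
  types <- factor(paste0("type", 1 + (seq_len(n) - 1) %% config$n_types))
  batch_names <- names(config$mosaic_pattern)
  batches <- factor(batch_names[1 + (seq_len(n) - 1) %/%
                                  ceiling(n / config$n_batches)],
                    levels = batch_names)

  centroids <- matrix(stats::rnorm(config$n_types * d, sd = 3),
                      config$n_types, d)
  latent <- centroids[as.integer(types), , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = config$noise_scale), n, d)

  # shared latent batch offset; direction fixed by seed, magnitude by scale
  batch_offsets <- matrix(stats::rnorm(config$n_batches * d), config$n_batches, d) *
    config$batch_effect_scale
  latent_obs <- latent + batch_offsets[as.integer(batches), , drop = FALSE]

  barcodes <- sprintf("cell%04d", seq_len(n))
  counts <- list()
  for (m in config$modalities) {
    p <- config$n_features[[m]]
    W <- matrix(stats::rnorm(d * p, sd = 1 / sqrt(d)), d, p)
    # small per-batch, per-modality feature-space shift
    mod_off <- matrix(stats::rnorm(config$n_batches * p, sd = 0.1), config$n_batches, p) *
      config$batch_effect_scale
    eta <- latent_obs %*% W + mod_off[as.integer(batches), , drop = FALSE]
    rate <- exp(eta - apply(eta, 1, max))       # per-cell softmax-style rates
    rate <- rate / rowSums(rate) * config$library_size[[m]]
    x <- matrix(0L, n, p)
    if (m == "atac") {
      lam <- pmin(rate, 50)
      x[] <- stats::rpois(n * p, lambda = lam)
      x[] <- stats::rbinom(n * p, size = x, prob = 0.5)  # Bernoulli thinning
    } else {
      x[] <- stats::rnbinom(n * p, mu = rate, size = config$dispersion[[m]])
    }
    dimnames(x) <- list(barcodes, paste0(m, "_f", seq_len(p)))
    counts[[m]] <- x
  }

  mask <- matrix(FALSE, n, length(config$modalities),
                 dimnames = list(barcodes, config$modalities))
  for (b in batch_names)
    mask[batches == b, config$mosaic_pattern[[b]]] <- TRUE
  for (m in config$modalities)
    counts[[m]][!mask[, m], ] <- 0L

  ds <- mosaic_dataset(counts, batch = batches, mask = mask, labels = types,
                       barcodes = barcodes)
  rownames(latent) <- barcodes
  list(dataset = ds, latent = latent, config = config)
}

#' Hide cell-type labels to create a semi-supervised dataset
#'
#' Keeps labels for a stratified uniform draw of `fraction` of the cells and
#' masks the rest with `NA`. Stratification is by type, rounding the kept
#' count per type up, so every type retains at least one label whenever
#' `fraction > 0`.
#'
#' @param ds A fully labeled [mosaic_dataset()].
#' @param fraction Fraction of cells to keep labeled, in `[0, 1]`.
#' @param seed Integer seed for the draw.
#' @return A [mosaic_dataset()] with partially hidden labels.
#' @export
make_semisupervised <- function(ds, fraction, seed = 1L) {
  validate_mosaic(ds)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must be in [0, 1]")
  labels <- as.character(ds$labels)
  keep <- rep(FALSE, ds$n_cells)
  if (fraction > 0) {
    set.seed(derive_seed(seed, "semisup"))
    for (tp in unique(labels[!is.na(labels)])) {
      idx <- which(labels == tp)
      n_keep <- max(1L, ceiling(fraction * length(idx)))
      keep[sample(idx, n_keep)] <- TRUE
    }
  }
  labels[!keep] <- NA_character_
  ds$labels <- factor(labels, levels = levels(ds$labels))
  ds
}
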