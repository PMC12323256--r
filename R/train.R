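#' Training configuration
#'
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size; recon/KL/graph terms are rescaled by
#'   `n_cells / batch_size` so the loss weights keep their full-data meaning.
#' @param learning_rate Adam step size.
#' @param latent_dim,hidden Model architecture (see [init_model_params()]).
#' @param k Mutual-KNN neighbors for the per-modality graphs.
#' @param n_pairs Contrastive positive pairs `T` sampled per modality per
#'   mini-batch (from the edges induced on the batch).
#' @param n_triplets Triplets `H` sampled per mini-batch from its labeled
#'   cells.
#' @param tau InfoNCE temperature.
#' @param margin Triplet hinge margin.
#' @param weights A [loss_weights()].
#' @param seed Integer; fixes initialization, shuffling, pair/triplet
#'   sampling and reparameterization noise.
#' @return A `TrainConfig` list.
#' @export
train_config <- function(epochs = 200, batch_size = 128, learning_rate = 1e-3,
                         latent_dim = 20, hidden = 128, k = 15,
                         n_pairs = 50, n_triplets = 50, tau = 0.5,
                         margin = 5.0, weights = loss_weights(), seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, latent_dim >= 1,
            hidden >= 1, k >= 0, n_pairs >= 2, n_triplets >= 1, tau > 0,
            margin >= 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, latent_dim = latent_dim,
                 hidden = hidden, k = k, n_pairs = n_pairs,
                 n_triplets = n_triplets, tau = tau, margin = margin,
                 weights = weights, seed = as.integer(seed)),
            class = "TrainConfig")
}

adam_init <- function(params) {
  list(m = zeros_like(params$modalities), v = zeros_like(params$modalities),
       t = 0L)
}

adam_walk <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(p)) {
    out <- list(p = p, m = m, v = v)
    for (nm in names(p)) {
      r <- adam_walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, beta1, beta2, eps)
      out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
    }
    return(out)
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# Per-modality ordered edge lists (global indices) from a NeighborGraph.
ordered_edges <- function(graph) {
  lapply(graph$adjacency, function(adj) Matrix::which(adj != 0, arr.ind = TRUE))
}

# Restrict global ordered edges to a mini-batch, re-indexed locally.
induce_edges <- function(edges_global, cells) {
  local_of <- integer(0)
  local_of[cells] <- seq_along(cells)
  lapply(edges_global, function(e) {
    keep <- e[, 1] %in% cells & e[, 2] %in% cells
    e <- e[keep, , drop = FALSE]
    cbind(local_of[e[, 1]], local_of[e[, 2]])
  })
}

#' Train the mosaic product-of-experts VAE
#'
#' Builds the per-modality mutual-KNN graphs once on the preprocessed views,
#' then optimizes the combined objective (reconstruction + KL + graph
#' cross-entropy + InfoNCE + triplet) with Adam over shuffled mini-batches.
#' Within each mini-batch, graph edges are the induced subgraph, positive
#' pairs are resampled from those edges, and triplets are resampled from the
#' batch's labeled cells, so pair/triplet sets are fresh every pass. If
#' fewer than two labeled classes exist the triplet weight is forced to zero
#' with a warning. The run is bitwise deterministic given the seed
#' (single-threaded).
#'
#' @param pre A `PreprocessedDataset` from [preprocess()].
#' @param ds The matching [mosaic_dataset()].
#' @param cfg A [train_config()].
#' @return List with `params` (trained `ModelParams`), `embedding` (the
#'   fused posterior means, cells x latent_dim), `history` (one row per
#'   epoch: mean per-batch loss components, on the full-data scale), `graph`
#'   (the `NeighborGraph` used), and `cfg`.
#' @export
train <- function(pre, ds, cfg = train_config()) {
  validate_mosaic(ds)
  stopifnot(inherits(cfg, "TrainConfig"))
  n <- ds$n_cells
  feature_dims <- vapply(pre$views, ncol, integer(1))
  params <- init_model_params(feature_dims, cfg$latent_dim, cfg$hidden,
                              seed = cfg$seed)
  graph <- build_neighbor_graphs(pre, ds, k = cfg$k)
  edges_global <- ordered_edges(graph)

  labels_chr <- as.character(ds$labels)
  lab_classes <- unique(labels_chr[!is.na(labels_chr)])
  lab_counts <- table(labels_chr)
  weights <- cfg$weights
  if (isTRUE(weights$extensive)) {
    # put the intensive (mean / 1/N) terms on the same extensive scale as
    # the summed reconstruction and KL terms
    weights$graph <- weights$graph * n
    weights$contrastive <- weights$contrastive * n
    weights$triplet <- weights$triplet * n
  }
  if (weights$triplet > 0 &&
      (length(lab_classes) < 2 || !any(lab_counts >= 2))) {
    warning("fewer than 2 labeled classes; triplet weight forced to 0",
            call. = FALSE)
    weights$triplet <- 0
  }

  opt <- adam_init(params)
  history <- vector("list", cfg$epochs)
  set.seed(derive_seed(cfg$seed, "train"))

  for (epoch in seq_len(cfg$epochs)) {
    order_ <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    comp_sums <- c(recon = 0, kl = 0, graph = 0, contrastive = 0,
                   triplet = 0, total = 0)
    for (s in starts) {
      cells <- order_[s:min(s + cfg$batch_size - 1, n)]
      nB <- length(cells)
      eps <- matrix(stats::rnorm(nB * cfg$latent_dim), nB, cfg$latent_dim)
      edges <- induce_edges(edges_global, cells)

      pairs <- lapply(edges, function(e) {
        und <- e[e[, 1] < e[, 2], , drop = FALSE]
        if (nrow(und) == 0) return(NULL)
        pick <- sample.int(nrow(und), cfg$n_pairs, replace = TRUE)
        flip <- stats::runif(cfg$n_pairs) < 0.5
        p <- und[pick, , drop = FALSE]
        p[flip, ] <- p[flip, c(2, 1), drop = FALSE]
        p
      })

      triplets <- NULL
      if (weights$triplet > 0) {
        lab_b <- labels_chr[cells]
        triplets <- tryCatch({
          ts <- sample_triplets(lab_b, cfg$n_triplets,
                                seed = sample.int(2^30, 1),
                                margin = cfg$margin)
          ts$triplets
        }, error = function(e) NULL)
      }

      res <- vae_batch_grad(params, pre$views, ds$mask, cells, eps, edges,
                            pairs, triplets, weights, cfg$tau, cfg$margin,
                            scale = n / nB, n_total = n)
      if (!is.finite(res$total)) {
        bad <- names(res$components)[!vapply(res$components, is.finite,
                                             logical(1))]
        stop("training diverged at epoch ", epoch, " (non-finite: ",
             paste(c(bad, if (!length(bad)) "total"), collapse = ", "), ")")
      }
      opt$t <- opt$t + 1L
      upd <- adam_walk(params$modalities, res$grads, opt$m, opt$v,
                       cfg$learning_rate, opt$t)
      params$modalities <- upd$p; opt$m <- upd$m; opt$v <- upd$v
      comp_sums <- comp_sums + c(unlist(res$components), total = res$total)
    }
    history[[epoch]] <- as.list(comp_sums / length(starts))
  }

  history_df <- if (cfg$epochs > 0) {
    cbind(data.frame(epoch = seq_len(cfg$epochs)),
          do.call(rbind, lapply(history, as.data.frame)))
  } else {
    data.frame(epoch = integer(0), recon = numeric(0), kl = numeric(0),
               graph = numeric(0), contrastive = numeric(0),
               triplet = numeric(0), total = numeric(0))
  }

  list(params = params, embedding = embed(pre, ds, params),
       history = history_df, graph = graph, cfg = cfg)
}

#' Embed a dataset with trained parameters
#'
#' Returns the fused posterior means (no sampling): each cell's available
#' modalities are encoded and combined by the product-of-experts rule, and
#' the fused mean is the embedding — the standard choice for downstream
#' clustering. Deterministic.
#'
#' @param pre A `PreprocessedDataset`.
#' @param ds The matching [mosaic_dataset()].
#' @param params Trained `ModelParams` covering every modality in the mask.
#' @return Cells x latent_dim matrix, rownames = barcodes.
#' @export
embed <- function(pre, ds, params) {
  missing_m <- setdiff(colnames(ds$mask)[colSums(ds$mask) > 0],
                       names(params$modalities))
  if (length(missing_m))
    stop("mask uses modalities unknown to the model: ",
         paste(missing_m, collapse = ", "))
  n <- ds$n_cells
  d <- params$latent_dim
  means <- list(); vars <- list(); contrib <- list()
  for (m in names(params$modalities)) {
    avail <- which(ds$mask[, m])
    mu_full <- matrix(0, n, d); var_full <- matrix(1, n, d)
    cm <- rep(0, n)
    if (length(avail)) {
      post <- encode_modality(pre$views[[m]][avail, , drop = FALSE],
                              params, m)
      mu_full[avail, ] <- post$mean; var_full[avail, ] <- post$var
      cm[avail] <- 1
    }
    means[[m]] <- mu_full; vars[[m]] <- var_full; contrib[[m]] <- cm
  }
  fused <- poe_fuse_matrix(means, vars, contrib)
  out <- fused$mean
  rownames(out) <- ds$barcodes
  out
}
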