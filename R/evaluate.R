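# Clustering and integration-benchmarking metrics for embeddings with known
# cell-type and batch annotations.

# Exact Euclidean KNN: n x k matrix of neighbor indices (self excluded),
# ties broken by lower index.
knn_indices <- function(z, k) {
  n <- nrow(z)
  if (n < k + 1) stop("need at least k_neighbors + 1 cells")
  d2 <- as.matrix(stats::dist(z))^2
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

knn_igraph <- function(z, k) {
  nn <- knn_indices(z, k)
  el <- cbind(rep(seq_len(nrow(z)), each = k), as.integer(t(nn)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)   # union of directed KNN, duplicate edges merged
}

#' Leiden clustering on a KNN graph of the embedding
#'
#' Builds an exact Euclidean k-nearest-neighbor graph on the embedding and
#' runs Leiden community detection with the modularity objective.
#'
#' @param z Embedding matrix (cells x dims), finite.
#' @param k_neighbors Neighbors per cell for the graph.
#' @param resolution Leiden resolution parameter (larger = more clusters).
#' @param seed Integer seed for the Leiden refinement randomness.
#' @return Integer cluster labels, one per cell.
#' @export
leiden_cluster <- function(z, k_neighbors = 15, resolution = 1.0, seed = 1L) {
  z <- as.matrix(z)
  stopifnot(all(is.finite(z)), k_neighbors >= 1)
  g <- knn_igraph(z, k_neighbors)
  set.seed(derive_seed(seed, "leiden"))
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  as.integer(igraph::membership(cl))
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two
#' partition entropies; symmetric and invariant to label renaming.
#'
#' @param a,b Two label vectors of equal length.
#' @return Real in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  igraph::compare(a, b, method = "nmi")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions, around 0 for
#' independent ones (can be negative).
#'
#' @param a,b Two label vectors of equal length.
#' @return Real in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  igraph::compare(a, b, method = "adjusted.rand")
}

#' Graph connectivity of cell-type neighborhoods
#'
#' For each cell-type label, takes the subgraph of the embedding KNN graph
#' induced by that type's cells and scores the fraction of them lying in its
#' largest connected component; the score is the mean over types. 1 means
#' every type forms a single connected neighborhood (no type is split, e.g.
#' by batch). Types with fewer than 2 cells are excluded with a warning.
#'
#' @param z Embedding matrix.
#' @param labels Per-cell type labels (all cells labeled).
#' @param k_neighbors KNN graph size.
#' @return Real in `(0, 1]`.
#' @export
graph_connectivity <- function(z, labels, k_neighbors = 15) {
  g <- knn_igraph(as.matrix(z), k_neighbors)
  labels <- as.character(labels)
  fracs <- c()
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    if (length(idx) < 2) {
      warning("label '", lab, "' has < 2 cells; excluded from connectivity",
              call. = FALSE)
      next
    }
    sub <- igraph::induced_subgraph(g, idx)
    comp <- igraph::components(sub)
    fracs <- c(fracs, max(comp$csize) / length(idx))
  }
  mean(fracs)
}

# Local inverse Simpson index per cell on the embedding KNN graph:
# perplexity-calibrated Gaussian weights over each cell's nearest
# neighbors, then 1 / sum_b p_b^2 over the label distribution.
lisi_scores <- function(z, labels, perplexity = 30) {
  z <- as.matrix(z)
  labels <- as.integer(factor(labels))
  n <- nrow(z)
  k <- min(3 * perplexity, n - 1)
  d2 <- as.matrix(stats::dist(z))^2
  diag(d2) <- Inf
  target <- log(perplexity)
  vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    di <- d2[i, nb]
    # binary search for the kernel precision matching the target perplexity
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      h <- log(sw) + beta * sum(di * w) / sw
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta); p_ <- w / sum(w)
    probs <- vapply(split(p_, labels[nb]), sum, numeric(1))
    1 / sum(probs^2)
  }, numeric(1))
}

#' Graph iLISI: batch-mixing score
#'
#' Mean local inverse Simpson index of the batch labels over each cell's
#' KNN neighborhood (perplexity 30), rescaled to `[0, 1]` as
#' `(score - 1) / (n_batches - 1)`. 1 = batches perfectly mixed locally.
#'
#' @param z Embedding matrix.
#' @param batches Per-cell batch labels.
#' @param perplexity Neighborhood size parameter.
#' @return Real in `[0, 1]`.
#' @export
ilisi <- function(z, batches, perplexity = 30) {
  b <- length(unique(batches))
  if (b < 2) return(NA_real_)
  s <- mean(lisi_scores(z, batches, perplexity))
  (s - 1) / (b - 1)
}

#' Graph cLISI: cell-type purity score
#'
#' Mean local inverse Simpson index of the type labels, rescaled as
#' `(n_types - score) / (n_types - 1)`. 1 = every neighborhood is a single
#' type (perfect separation).
#'
#' @param z Embedding matrix.
#' @param labels Per-cell type labels.
#' @param perplexity Neighborhood size parameter.
#' @return Real in `[0, 1]`.
#' @export
clisi <- function(z, labels, perplexity = 30) {
  t_ <- length(unique(labels))
  if (t_ < 2) return(NA_real_)
  s <- mean(lisi_scores(z, labels, perplexity))
  (t_ - s) / (t_ - 1)
}

#' Benchmark an embedding against known types and batches
#'
#' Clusters the embedding with Leiden and reports the standard integration
#' metrics: NMI and ARI of clusters vs. types, graph connectivity of type
#' neighborhoods, graph iLISI (batch mixing) and graph cLISI (type purity).
#'
#' @param z Embedding matrix (cells x dims).
#' @param type_labels Per-cell type labels covering all cells.
#' @param batch_labels Per-cell batch labels.
#' @param k_neighbors KNN graph size for clustering and metrics.
#' @param resolution Leiden resolution.
#' @param seed Integer seed.
#' @return An `EvalReport` list: `nmi`, `ari`, `graph_connectivity`,
#'   `ilisi`, `clisi`, `n_clusters`, plus the `clusters` vector.
#' @export
evaluate_embedding <- function(z, type_labels, batch_labels,
                               k_neighbors = 15, resolution = 1.0,
                               seed = 1L) {
  z <- as.matrix(z)
  stopifnot(length(type_labels) == nrow(z),
            length(batch_labels) == nrow(z))
  if (anyNA(type_labels)) stop("evaluation requires fully labeled cells")
  clusters <- leiden_cluster(z, k_neighbors, resolution, seed)
  structure(list(
    nmi = nmi(clusters, type_labels),
    ari = ari(clusters, type_labels),
    graph_connectivity = graph_connectivity(z, type_labels, k_neighbors),
    ilisi = ilisi(z, batch_labels),
    clisi = clisi(z, type_labels),
    n_clusters = length(unique(clusters)),
    clusters = clusters), class = "EvalReport")
}

#' @exportS3Method base::print
print.EvalReport <- function(x, ...) {
  cat("EvalReport:\n")
  for (nm in c("nmi", "ari", "graph_connectivity", "ilisi", "clisi"))
    cat(sprintf("  %-18s %.4f\n", nm, x[[nm]]))
  cat(sprintf("  %-18s %d\n", "n_clusters", x$n_clusters))
  invisible(x)
}

#' Concatenated-PCA baseline embedding
#'
#' The no-integration reference: per-modality views are column-concatenated
#' (entries of unavailable modalities set to 0), centered, and projected
#' onto the top principal components. Deterministic.
#'
#' @param pre A `PreprocessedDataset`.
#' @param n_dims Output dimensionality.
#' @return Cells x `n_dims` score matrix.
#' @export
pca_baseline <- function(pre, n_dims = 20) {
  x <- do.call(cbind, lapply(pre$views, function(v) {
    v[is.na(v)] <- 0
    v
  }))
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = 0, nv = n_dims)
  scores <- x %*% sv$v
  rownames(scores) <- rownames(pre$views[[1]])
  scores
}
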