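#' Cosine similarity between two feature vectors
#'
#' `dot(x, y) / (|x| |y|)`, the similarity the neighbor graphs are built on.
#'
#' @param x,y Numeric vectors of equal length, both nonzero.
#' @return A real in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

# All-pairs cosine similarity of the rows of x (no zero rows allowed).
cosine_matrix <- function(x) {
  xn <- l2_normalize_rows(x)
  tcrossprod(xn)
}

#' Build a mutual k-nearest-neighbor adjacency matrix
#'
#' Among the available cells, cell `j` is a candidate neighbor of `i` when it
#' is in `i`'s top-`k` by cosine similarity (self excluded); the edge
#' `A[i, j] = A[j, i] = 1` exists only when each cell is in the other's
#' top-`k` (mutual neighbors). Ties in similarity are broken by lower cell
#' index for determinism. Unavailable cells get all-zero rows and columns.
#'
#' @param view Cell x feature matrix (rows for unavailable cells are ignored
#'   and may be `NA`).
#' @param available Logical vector marking usable cells; defaults to rows
#'   with no `NA`.
#' @param k Neighbors per cell (`k = 0` gives an empty graph).
#' @return A symmetric binary sparse adjacency matrix with zero diagonal.
#' @export
build_mutual_knn <- function(view, available = NULL, k = 15) {
  stopifnot(k >= 0)
  if (is.null(available)) available <- !apply(view, 1, anyNA)
  n <- nrow(view)
  idx <- which(available)
  if (k > 0 && length(idx) < k + 1)
    stop("need at least k+1 available cells")
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n),
                                dimnames = list(rownames(view), rownames(view)))
  if (k == 0 || length(idx) == 0) return(empty)
  sub <- view[idx, , drop = FALSE]
  zero <- rowSums(sub^2) == 0
  if (any(zero))
    stop("all-zero available row(s): ",
         paste(utils::head((rownames(view) %||% as.character(seq_len(n)))[idx[zero]], 5),
               collapse = ", "))
  sim <- cosine_matrix(sub)
  diag(sim) <- -Inf
  ns <- length(idx)
  # directed top-k; order() breaks ties by ascending index
  nn <- t(apply(sim, 1, function(s) order(s, decreasing = TRUE)[seq_len(k)]))
  directed <- Matrix::sparseMatrix(i = rep(seq_len(ns), each = k),
                                   j = as.integer(t(nn)),
                                   x = 1, dims = c(ns, ns))
  mutual <- directed * Matrix::t(directed)   # 1 iff both directions present
  out <- empty
  out[idx, idx] <- mutual
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Build the per-modality mutual-KNN neighbor graphs
#'
#' One adjacency matrix per modality, computed on that modality's
#' preprocessed view over the cells where the modality is available.
#'
#' @param pre A `PreprocessedDataset` from [preprocess()].
#' @param ds The matching [mosaic_dataset()] (for the availability mask).
#' @param k Neighbors per cell.
#' @return A `NeighborGraph`: list with `adjacency` (named list of sparse
#'   matrices) and `k`.
#' @export
build_neighbor_graphs <- function(pre, ds, k = 15) {
  adjacency <- list()
  for (m in names(pre$views))
    adjacency[[m]] <- build_mutual_knn(pre$views[[m]], ds$mask[, m], k = k)
  structure(list(adjacency = adjacency, k = k), class = "NeighborGraph")
}

# Edge list (i < j) of a sparse symmetric adjacency matrix.
edge_list <- function(adj) {
  tri <- Matrix::which(adj != 0, arr.ind = TRUE)
  tri[tri[, 1] < tri[, 2], , drop = FALSE]
}

#' Export a neighbor graph as coordinate triplets
#'
#' Writes one row per undirected edge: `modality<TAB>i<TAB>j` (1-based).
#'
#' @param graph A `NeighborGraph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_graph_tsv <- function(graph, path) {
  rows <- do.call(rbind, lapply(names(graph$adjacency), function(m) {
    e <- edge_list(graph$adjacency[[m]])
    if (nrow(e) == 0) return(NULL)
    data.frame(modality = m, i = e[, 1], j = e[, 2])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample positive pairs from the neighbor graphs
#'
#' For each modality, draws `T` edges uniformly with replacement from that
#' modality's mutual-KNN graph (each pair oriented at random); these are the
#' positive pairs the InfoNCE contrastive loss contrasts against the rest of
#' the sample. A modality whose graph has no edges is skipped with a warning.
#'
#' @param graph A `NeighborGraph`.
#' @param n_pairs Number of pairs `T` per modality.
#' @param seed Integer seed.
#' @param tau InfoNCE temperature carried alongside the pairs.
#' @return A `PairSet`: list with `pairs` (named list of `T x 2` index
#'   matrices), `n_pairs`, `tau`.
#' @export
sample_positive_pairs <- function(graph, n_pairs, seed = 1L, tau = 0.5) {
  stopifnot(n_pairs >= 1, tau > 0)
  set.seed(derive_seed(seed, "pairs"))
  pairs <- list()
  for (m in names(graph$adjacency)) {
    e <- edge_list(graph$adjacency[[m]])
    if (nrow(e) == 0) {
      warning("no edges in modality '", m, "'; skipping", call. = FALSE)
      next
    }
    pick <- sample.int(nrow(e), n_pairs, replace = TRUE)
    flip <- stats::runif(n_pairs) < 0.5
    p <- e[pick, , drop = FALSE]
    p[flip, ] <- p[flip, c(2, 1), drop = FALSE]
    dimnames(p) <- list(NULL, c("anchor", "positive"))
    pairs[[m]] <- p
  }
  structure(list(pairs = pairs, n_pairs = n_pairs, tau = tau),
            class = "PairSet")
}

#' Sample anchor/positive/negative triplets from labeled cells
#'
#' Each triplet is an anchor cell, a distinct cell of the same type, and a
#' cell of a different type — the supervision unit of the triplet margin
#' loss. Anchors are drawn uniformly from labeled cells whose class has at
#' least two members; sampling is global across batches, so same-type pairs
#' may span batches (which is what drives batch alignment).
#'
#' @param labels Per-cell labels (factor or character); `NA` = unlabeled.
#' @param n_triplets Number of triplets `H`.
#' @param seed Integer seed.
#' @param margin Hinge margin carried alongside the triplets.
#' @return A `TripletSet`: list with `triplets` (`H x 3` index matrix with
#'   columns anchor/positive/negative), `n_triplets`, `margin`.
#' @export
sample_triplets <- function(labels, n_triplets, seed = 1L, margin = 1.0) {
  stopifnot(n_triplets >= 1, margin >= 0)
  labels <- as.character(labels)
  labeled <- which(!is.na(labels))
  if (length(labeled) == 0) stop("no labeled cells")
  classes <- unique(labels[labeled])
  if (length(classes) < 2) stop("need at least 2 labeled classes")
  counts <- table(labels[labeled])
  anchor_pool <- labeled[counts[labels[labeled]] >= 2]
  if (length(anchor_pool) == 0) stop("no class has >= 2 labeled cells")
  set.seed(derive_seed(seed, "triplets"))
  a <- anchor_pool[sample.int(length(anchor_pool), n_triplets, replace = TRUE)]
  p <- vapply(a, function(ai) {
    pool <- setdiff(labeled[labels[labeled] == labels[ai]], ai)
    pool[sample.int(length(pool), 1)]
  }, integer(1))
  n <- vapply(a, function(ai) {
    pool <- labeled[labels[labeled] != labels[ai]]
    pool[sample.int(length(pool), 1)]
  }, integer(1))
  trip <- cbind(anchor = a, positive = p, negative = n)
  structure(list(triplets = trip, n_triplets = n_triplets, margin = margin),
            class = "TripletSet")
}
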