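# The five objective terms and their weighted total. All are plain R
# functions of embeddings/posteriors so they can be unit-tested against
# independent oracles; the training loop re-derives their gradients in
# gradients.R.

#' Loss weights for the combined objective
#'
#' The total objective is
#' `lambda1*recon + lambda2*kl + lambda3*graph + lambda4*contrastive +
#' lambda5*triplet`. The reconstruction and KL terms are *extensive* — sums
#' over all cells (and features) — while the contrastive and triplet terms
#' are *means* over sampled pairs/triplets and the graph term carries a 1/N
#' factor, so with literal unit weights the three structure terms are
#' numerically invisible next to the reconstruction sum and the model
#' degenerates to a plain VAE. With `extensive = TRUE` (the default) the
#' graph, contrastive, and triplet weights are therefore interpreted
#' per-cell: [train()] multiplies them by the dataset size so all five
#' terms live on the same extensive scale. Defaults (1, 1, 1, 1, 5) keep
#' the proper ELBO weighting of reconstruction vs. KL and give the
#' supervised triplet term — the only term with explicitly cross-batch
#' positives — a stronger voice.
#'
#' @param recon,kl,graph,contrastive,triplet Non-negative finite reals.
#' @param extensive If `TRUE`, `graph`/`contrastive`/`triplet` are per-cell
#'   weights scaled by `n_cells` at training time; if `FALSE` they are used
#'   literally.
#' @return A `LossWeights` list.
#' @export
loss_weights <- function(recon = 1, kl = 1, graph = 1, contrastive = 1,
                         triplet = 5, extensive = TRUE) {
  w <- list(recon = recon, kl = kl, graph = graph,
            contrastive = contrastive, triplet = triplet)
  if (any(!vapply(w, function(x) is.finite(x) && x >= 0, logical(1))))
    stop("loss weights must be non-negative and finite")
  w$extensive <- isTRUE(extensive)
  structure(w, class = "LossWeights")
}

#' Reconstruction loss: summed squared error
#'
#' `sum over cells and available modalities of ||x - xhat||^2` — a sum, not
#' a mean, so cells and features all count equally.
#'
#' @param x,xhat Matrices (or named lists of matrices, one per modality) of
#'   identical shape.
#' @return Non-negative real.
#' @export
recon_loss <- function(x, xhat) {
  if (is.list(x)) {
    stopifnot(is.list(xhat), identical(names(x), names(xhat)))
    return(sum(vapply(names(x), function(m) recon_loss(x[[m]], xhat[[m]]),
                      numeric(1))))
  }
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!identical(dim(x), dim(xhat))) stop("shape mismatch in recon_loss")
  sum((x - xhat)^2)
}

#' KL divergence from the posterior to the standard-normal prior
#'
#' Closed form for diagonal Gaussians, summed over cells and latent
#' dimensions: `0.5 * sum(var + mean^2 - 1 - log(var))`.
#'
#' @param post A `GaussianPosterior` (`mean`, `var` vectors or matrices).
#' @return Non-negative real.
#' @export
kl_loss <- function(post) {
  mu <- as.matrix(post$mean); v <- as.matrix(post$var)
  if (any(v <= 0)) stop("kl_loss requires strictly positive variances")
  0.5 * sum(v + mu^2 - 1 - log(v))
}

#' Graph cross-entropy loss
#'
#' The latent space should reproduce each modality's mutual-KNN adjacency:
#' with `A_r = sigmoid(Z Z^T)` (cell x cell), the loss is
#' `-(1/N) * sum over modalities and over ordered pairs with A^m_ij = 1 of
#' log A_r_ij`. Only observed edges contribute; `log(sigmoid())` is
#' evaluated in a numerically stable form.
#'
#' @param z Embedding matrix, one row per cell.
#' @param graph A `NeighborGraph` (cell indices must match `z` rows).
#' @param n_total Denominator `N`; defaults to `nrow(z)`. During mini-batch
#'   training the full dataset size is passed here.
#' @return Non-negative real (0 when no modality has edges).
#' @export
graph_loss <- function(z, graph, n_total = nrow(z)) {
  z <- as.matrix(z)
  total <- 0
  for (m in names(graph$adjacency)) {
    adj <- graph$adjacency[[m]]
    e <- Matrix::which(adj != 0, arr.ind = TRUE)   # ordered pairs, both directions
    if (nrow(e) == 0) next
    s <- rowSums(z[e[, 1], , drop = FALSE] * z[e[, 2], , drop = FALSE])
    total <- total - sum(log_sigmoid(s))
  }
  total / n_total
}

# Cosine-similarity matrix between rows of u and rows of v.
cross_cosine <- function(u, v) {
  tcrossprod(l2_normalize_rows(u), l2_normalize_rows(v))
}

# InfoNCE for one modality's pair set. anchors/positives: T x d embeddings.
info_nce_modality <- function(anchors, positives, tau) {
  n_pairs <- nrow(anchors)
  if (n_pairs < 2) stop("info_nce_loss needs at least 2 pairs per modality")
  s <- cross_cosine(anchors, positives) / tau   # s[i, j] = sim(a_i, p_j)/tau
  total <- 0
  for (i in seq_len(n_pairs)) {
    # l(a_i, p_i): denominator sums exp(sim(a_i, p_j)), j != i,
    # plus exp(sim(a_j, p_i)) over all j
    d1 <- logsumexp(c(s[i, -i], s[, i]))
    # l(p_i, a_i): roles swapped
    d2 <- logsumexp(c(s[-i, i], s[i, ]))
    total <- total + (s[i, i] - d1) + (s[i, i] - d2)
  }
  -total / (2 * n_pairs)
}

#' InfoNCE contrastive loss over neighbor-derived positive pairs
#'
#' For each modality, every sampled positive pair is scored against all
#' other pair members in the set: the log-ratio of the exponentiated
#' (temperature-scaled) cosine similarity of the pair to the sum over the
#' competing similarities, symmetrized over the pair's two orientations and
#' averaged over the `T` pairs; modalities are then summed.
#'
#' @param z Embedding matrix, one row per cell.
#' @param pairs A `PairSet` from [sample_positive_pairs()].
#' @return Real (can be negative when positives dominate).
#' @export
info_nce_loss <- function(z, pairs) {
  z <- as.matrix(z)
  stopifnot(pairs$tau > 0)
  total <- 0
  for (m in names(pairs$pairs)) {
    p <- pairs$pairs[[m]]
    total <- total + info_nce_modality(z[p[, 1], , drop = FALSE],
                                       z[p[, 2], , drop = FALSE],
                                       pairs$tau)
  }
  total
}

#' Triplet margin loss on labeled cells
#'
#' Mean over triplets of `max(d(a, p) - d(a, n) + margin, 0)` with `d`
#' Euclidean distance in the latent space: anchors must sit closer to their
#' same-type positive than to their different-type negative by the margin.
#'
#' @param z Embedding matrix, one row per cell.
#' @param triplets A `TripletSet` from [sample_triplets()].
#' @return Non-negative real.
#' @export
triplet_loss <- function(z, triplets) {
  z <- as.matrix(z)
  t_ <- triplets$triplets
  d_ap <- sqrt(rowSums((z[t_[, 1], , drop = FALSE] - z[t_[, 2], , drop = FALSE])^2))
  d_an <- sqrt(rowSums((z[t_[, 1], , drop = FALSE] - z[t_[, 3], , drop = FALSE])^2))
  mean(pmax(d_ap - d_an + triplets$margin, 0))
}

#' Weighted total of the five loss components
#'
#' @param components List/`LossReport` with elements `recon`, `kl`, `graph`,
#'   `contrastive`, `triplet` (finite reals).
#' @param weights A [loss_weights()].
#' @return The scalar total.
#' @export
total_loss <- function(components, weights) {
  vals <- unlist(components[c("recon", "kl", "graph", "contrastive", "triplet")])
  if (any(!is.finite(vals))) stop("non-finite loss component")
  sum(vals * unlist(weights[c("recon", "kl", "graph", "contrastive", "triplet")]))
}
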