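# Modular VAE: one Gaussian encoder and one decoder per modality, fused by a
# product of experts. Architecture: input -> ReLU(hidden) -> {linear mean,
# softplus variance}; decoder latent -> ReLU(hidden) -> linear output.
# All layers are plain dense matrices so gradients (gradients.R) stay exact.

VAR_FLOOR <- 1e-6

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize model parameters for a mosaic VAE
#'
#' One encoder and one decoder per modality. Default architecture is a
#' single hidden layer of 128 ReLU units on each side, a linear mean head
#' and a softplus variance head (so variances are strictly positive), and a
#' 20-dimensional latent space.
#'
#' @param feature_dims Named integer vector: features per modality.
#' @param latent_dim Latent dimensionality.
#' @param hidden Hidden-layer width.
#' @param seed Integer seed for the initialization draw.
#' @return A `ModelParams` list: per modality `enc` (`W1`, `b1`, `Wmu`,
#'   `bmu`, `Ws`, `bs`) and `dec` (`W1`, `b1`, `W2`, `b2`), plus
#'   `latent_dim`, `hidden`, `modalities`, `feature_dims`.
#' @export
init_model_params <- function(feature_dims, latent_dim = 20, hidden = 128,
                              seed = 1L) {
  set.seed(derive_seed(seed, "init"))
  params <- list()
  for (m in names(feature_dims)) {
    p <- feature_dims[[m]]
    params[[m]] <- list(
      enc = list(W1 = glorot(p, hidden), b1 = numeric(hidden),
                 Wmu = glorot(hidden, latent_dim), bmu = numeric(latent_dim),
                 Ws = glorot(hidden, latent_dim), bs = numeric(latent_dim)),
      dec = list(W1 = glorot(latent_dim, hidden), b1 = numeric(hidden),
                 W2 = glorot(hidden, p), b2 = numeric(p))
    )
  }
  structure(list(modalities = params, latent_dim = latent_dim,
                 hidden = hidden, feature_dims = feature_dims),
            class = "ModelParams")
}

add_bias <- function(x, b) sweep(x, 2, b, `+`)

#' Encode one modality into a per-cell Gaussian posterior
#'
#' Runs the modality's encoder on the given view rows and returns the
#' diagonal-Gaussian posterior parameters. The variance head uses a softplus
#' link plus a small floor, so variances are strictly positive and the
#' product-of-experts precisions stay finite.
#'
#' @param x View rows (cells with this modality available) x features.
#' @param params A `ModelParams` object.
#' @param modality Modality name.
#' @return A `GaussianPosterior`: list with `mean` and `var` (cells x
#'   latent_dim), all variances `> 0`.
#' @export
encode_modality <- function(x, params, modality) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite input to encoder '", modality, "'")
  enc <- params$modalities[[modality]]$enc
  h <- relu(add_bias(x %*% enc$W1, enc$b1))
  post <- list(mean = add_bias(h %*% enc$Wmu, enc$bmu),
               var = softplus(add_bias(h %*% enc$Ws, enc$bs)) + VAR_FLOOR)
  structure(post, class = "GaussianPosterior")
}

#' Fuse Gaussian experts by a product of experts
#'
#' Multiplying the expert densities with the standard-normal prior gives
#' another diagonal Gaussian whose precision is one plus the sum of expert
#' precisions and whose mean is the precision-weighted average of expert
#' means: `var = (1 + sum(1/var_m))^-1`, `mean = (sum(mean_m/var_m)) * var`,
#' elementwise. With no experts the result is the prior itself.
#'
#' @param experts List of `GaussianPosterior`-like lists (`mean`, `var`),
#'   each a vector or single-row matrix for one cell; may be empty.
#' @param latent_dim Required when `experts` is empty.
#' @return A `GaussianPosterior` with the fused `mean` and `var`.
#' @export
poe_combine <- function(experts, latent_dim = NULL) {
  if (length(experts) == 0) {
    if (is.null(latent_dim)) stop("latent_dim required with no experts")
    return(structure(list(mean = numeric(latent_dim),
                          var = rep(1, latent_dim)),
                     class = "GaussianPosterior"))
  }
  d <- length(as.numeric(experts[[1]]$mean))
  prec <- rep(1, d)       # unit-variance prior expert
  wsum <- numeric(d)
  for (e in experts) {
    v <- as.numeric(e$var)
    if (any(v <= 0)) stop("expert variances must be strictly positive")
    prec <- prec + 1 / v
    wsum <- wsum + as.numeric(e$mean) / v
  }
  structure(list(mean = wsum / prec, var = 1 / prec),
            class = "GaussianPosterior")
}

# Batched PoE over full-size matrices: contrib[[m]] is TRUE for rows where
# modality m is available; unavailable rows contribute nothing.
poe_fuse_matrix <- function(means, vars, contrib) {
  n <- nrow(means[[1]]); d <- ncol(means[[1]])
  prec <- matrix(1, n, d)
  wsum <- matrix(0, n, d)
  for (m in names(means)) {
    c_m <- as.numeric(contrib[[m]])
    prec <- prec + c_m * (1 / vars[[m]])
    wsum <- wsum + c_m * (means[[m]] / vars[[m]])
  }
  list(mean = wsum / prec, var = 1 / prec, prec = prec)
}

#' Draw latent representations by the reparameterization trick
#'
#' `z = mean + sqrt(var) * eps` with `eps` standard normal from the seeded
#' stream, so samples are deterministic given the seed and gradients can
#' flow through `mean` and `var`.
#'
#' @param post A `GaussianPosterior` (matrices cells x latent_dim).
#' @param seed Integer seed.
#' @return Latent matrix `Z`, same shape as `post$mean`.
#' @export
reparameterize <- function(post, seed = 1L) {
  mu <- as.matrix(post$mean)
  v <- as.matrix(post$var)
  set.seed(derive_seed(seed, "reparam"))
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + sqrt(v) * eps
}

#' Decode latent representations back into one modality's feature space
#'
#' @param z Latent matrix (cells x latent_dim), finite.
#' @param params A `ModelParams` object.
#' @param modality Modality name.
#' @return Reconstruction matrix, cells x that modality's feature count.
#' @export
decode_modality <- function(z, params, modality) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("non-finite latent input to decoder '", modality, "'")
  dec <- params$modalities[[modality]]$dec
  h <- relu(add_bias(z %*% dec$W1, dec$b1))
  add_bias(h %*% dec$W2, dec$b2)
}
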