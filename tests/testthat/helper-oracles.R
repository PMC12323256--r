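# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: grid integration for the product of experts,
# literal nested loops for InfoNCE, Monte Carlo for the KL divergence.

# Product of 1-D Gaussian expert densities with the standard-normal prior,
# renormalized by grid integration; returns the mean and variance.
poe_grid_oracle <- function(means, vars, lo = -15, hi = 15, step = 1e-3) {
  x <- seq(lo, hi, by = step)
  logd <- stats::dnorm(x, 0, 1, log = TRUE)
  for (i in seq_along(means))
    logd <- logd + stats::dnorm(x, means[i], sqrt(vars[i]), log = TRUE)
  d <- exp(logd - max(logd))
  d <- d / sum(d)
  mu <- sum(x * d)
  list(mean = mu, var = sum((x - mu)^2 * d))
}

# InfoNCE per the printed definition, as literal nested loops.
# anchors/positives: T x d; returns the one-modality loss.
nce_loop_oracle <- function(anchors, positives, tau) {
  csim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  Tn <- nrow(anchors)
  ell <- function(i, A, P) {
    num <- exp(csim(A[i, ], P[i, ]) / tau)
    d1 <- 0
    for (j in seq_len(Tn)) if (j != i) d1 <- d1 + exp(csim(A[i, ], P[j, ]) / tau)
    d2 <- 0
    for (j in seq_len(Tn)) d2 <- d2 + exp(csim(A[j, ], P[i, ]) / tau)
    log(num / (d1 + d2))
  }
  tot <- 0
  for (i in seq_len(Tn))
    tot <- tot + ell(i, anchors, positives) + ell(i, positives, anchors)
  -tot / (2 * Tn)
}

# Monte-Carlo KL(N(mu, v) || N(0, 1)) for diagonal 1-D Gaussians.
kl_mc_oracle <- function(mu, v, n = 1e6, seed = 42) {
  set.seed(seed)
  z <- stats::rnorm(n, mu, sqrt(v))
  lq <- stats::dnorm(z, mu, sqrt(v), log = TRUE)
  lp <- stats::dnorm(z, 0, 1, log = TRUE)
  est <- mean(lq - lp)
  se <- stats::sd(lq - lp) / sqrt(n)
  list(est = est, se = se)
}

# Brute-force mutual-KNN on a small matrix by all-pairs cosine enumeration.
mutual_knn_oracle <- function(x, k) {
  n <- nrow(x)
  s <- matrix(-Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    s[i, j] <- sum(x[i, ] * x[j, ]) / sqrt(sum(x[i, ]^2) * sum(x[j, ]^2))
  topk <- lapply(seq_len(n), function(i) order(s[i, ], decreasing = TRUE)[seq_len(k)])
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in topk[[i]])
    if (i %in% topk[[j]]) a[i, j] <- 1
  a
}
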