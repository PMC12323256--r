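two_blobs <- function(n_per = 100, gap = 20, d = 5, seed = 2) {
  set.seed(seed)
  z <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  list(z = z, labels = rep(c("a", "b"), each = n_per))
}

test_that("Leiden separates well-isolated blobs and is seeded", {
  tb <- two_blobs()
  # resolution matched to the coarse two-group granularity; at resolution 1
  # modularity happily splits 100-cell blobs into local sub-communities
  cl <- leiden_cluster(tb$z, k_neighbors = 15, resolution = 0.25, seed = 3)
  expect_equal(length(unique(cl)), 2)
  expect_equal(ari(cl, tb$labels), 1.0)
  expect_identical(cl, leiden_cluster(tb$z, k_neighbors = 15,
                                      resolution = 0.25, seed = 3))
  # vanishing resolution collapses a connected graph to one community
  one_blob <- tb$z[1:100, ]
  expect_equal(length(unique(leiden_cluster(one_blob, resolution = 1e-4,
                                            seed = 3))), 1)
  expect_error(leiden_cluster(tb$z[1:5, ], k_neighbors = 10), "cells")
})

test_that("NMI and ARI are symmetric, renaming-invariant, and hit known values", {
  a <- rep(1:4, each = 25)
  expect_equal(nmi(a, a), 1.0)
  expect_equal(ari(a, a), 1.0)
  b <- sample(letters[1:4])[a]   # renamed partition
  expect_equal(ari(a, b), 1.0)
  expect_equal(nmi(a, b), 1.0)
  set.seed(1)
  c_ <- sample(1:3, 100, replace = TRUE)
  expect_equal(nmi(a, c_), nmi(c_, a))
  expect_equal(ari(a, c_), ari(c_, a))
  expect_equal(ari(rep(1, 100), a), 0)   # one cluster vs 4 balanced labels
})

test_that("ARI agrees with the independent mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:5) {
    a <- sample(1:4, 200, replace = TRUE)
    b <- sample(1:3, 200, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("NMI with arithmetic-mean normalization matches a hand entropy computation", {
  ent <- function(x) { p <- table(x) / length(x); -sum(p * log(p)) }
  mi <- function(a, b) {
    pj <- table(a, b) / length(a)
    pa <- rowSums(pj); pb <- colSums(pj)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb))
      if (pj[i, j] > 0) s <- s + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
    s
  }
  set.seed(5)
  a <- sample(1:3, 150, replace = TRUE)
  b <- ifelse(runif(150) < 0.7, a, sample(1:3, 150, replace = TRUE))
  expect_equal(nmi(a, b), as.numeric(mi(a, b) / ((ent(a) + ent(b)) / 2)),
               tolerance = 1e-10)
})

test_that("random partitions score ARI near zero", {
  set.seed(33)
  aris <- replicate(10, {
    lab <- sample(1:4, 1000, replace = TRUE)
    cl <- sample(1:4, 1000, replace = TRUE)
    ari(cl, lab)
  })
  expect_true(all(abs(aris) < 0.05))
})

test_that("graph connectivity is 1 for connected types and drops for split types", {
  tb <- two_blobs()
  expect_equal(graph_connectivity(tb$z, tb$labels), 1.0)
  # put half of type "a" far away: its induced subgraph disconnects
  z2 <- tb$z
  z2[1:50, ] <- z2[1:50, ] + 200
  expect_lt(graph_connectivity(z2, tb$labels), 1.0)
  expect_warning(graph_connectivity(tb$z[1:21, ], c(rep("a", 20), "solo")),
                 "solo")
})

test_that("iLISI detects batch mixing and cLISI detects type purity", {
  set.seed(44)
  n <- 200
  z <- matrix(rnorm(n * 5), n, 5)
  batch <- rep(c("x", "y"), n / 2)
  mixed <- ilisi(z, batch)
  zoff <- z
  zoff[batch == "y", ] <- zoff[batch == "y", ] + 30
  split <- ilisi(zoff, batch)
  expect_gt(mixed, 0.8)
  expect_lt(split, 0.05)
  expect_gt(mixed, split)   # adding an artificial offset lowers iLISI

  tb <- two_blobs()
  expect_gt(clisi(tb$z, tb$labels), 0.99)
  expect_lt(clisi(tb$z, sample(tb$labels)), 0.5)
})

test_that("evaluate_embedding assembles a coherent report", {
  tb <- two_blobs()
  batch <- rep(c("x", "y"), 100)
  rep_ <- evaluate_embedding(tb$z, tb$labels, batch, resolution = 0.25,
                             seed = 7)
  expect_s3_class(rep_, "EvalReport")
  expect_equal(rep_$ari, 1.0)
  expect_equal(rep_$nmi, 1.0)
  expect_equal(rep_$n_clusters, 2)
  expect_equal(rep_$graph_connectivity, 1.0)
  expect_true(rep_$ilisi > 0.5)
  expect_true(rep_$clisi > 0.99)
  expect_error(evaluate_embedding(tb$z, c(NA, tb$labels[-1]), batch),
               "labeled")
})

test_that("the PCA baseline is deterministic with the requested dimensionality", {
  sim <- tiny_dataset(seed = 15)
  pre <- preprocess(sim$dataset)
  b1 <- pca_baseline(pre, 8)
  b2 <- pca_baseline(pre, 8)
  expect_equal(b1, b2)
  expect_equal(dim(b1), c(60, 8))
})
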