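make_graph <- function(edges, n) {
  adj <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                              j = c(edges[, 2], edges[, 1]),
                              x = 1, dims = c(n, n))
  structure(list(adjacency = list(rna = adj), k = 1), class = "NeighborGraph")
}

test_that("reconstruction loss is the summed squared error", {
  x <- matrix(c(1, 0), 1, 2)
  expect_equal(recon_loss(x, x), 0)
  expect_equal(recon_loss(x, matrix(0, 1, 2)), 1.0)
  X <- rbind(c(1, 1), c(2, 0))
  expect_equal(recon_loss(X, matrix(0, 2, 2)), 6.0)
  expect_equal(recon_loss(list(a = x, b = X),
                          list(a = x * 0, b = X * 0)), 7.0)
  expect_error(recon_loss(x, matrix(0, 2, 2)), "shape")
})

test_that("KL closed form matches known values and Monte Carlo", {
  expect_equal(kl_loss(list(mean = 0, var = 1)), 0)
  expect_equal(kl_loss(list(mean = 1, var = 1)), 0.5)
  expect_equal(kl_loss(list(mean = 0, var = 0.5)), 0.096574, tolerance = 1e-5)
  mc <- kl_mc_oracle(0, 0.5)
  expect_equal(kl_loss(list(mean = 0, var = 0.5)), mc$est, tolerance = 1e-2)
  expect_error(kl_loss(list(mean = 0, var = -1)), "positive")
})

test_that("KL matches Monte-Carlo estimates within 3 SE across random posteriors", {
  set.seed(77)
  for (i in 1:20) {
    mu <- runif(1, -2, 2); v <- runif(1, 0.2, 3)
    mc <- kl_mc_oracle(mu, v, n = 2e5, seed = i)
    expect_lt(abs(kl_loss(list(mean = mu, var = v)) - mc$est), 3 * mc$se)
  }
})

test_that("graph loss matches the sigmoid(0) hand value and is stable and monotone", {
  g <- make_graph(cbind(1, 2), 4)
  z0 <- matrix(0, 4, 3)
  expect_equal(graph_loss(z0, g), (2 / 4) * log(2))

  gempty <- make_graph(matrix(numeric(0), 0, 2), 4)
  expect_equal(graph_loss(z0, gempty), 0)

  # stable for inner products up to 1e4 in magnitude
  zbig <- rbind(c(100, 0, 0), c(-100, 0, 0), 0, 0)
  expect_true(is.finite(graph_loss(zbig, g)))
  zbig2 <- rbind(c(100, 0, 0), c(100, 0, 0), 0, 0)
  expect_true(is.finite(graph_loss(zbig2, g)) && graph_loss(zbig2, g) >= 0)

  # increasing an edge's inner product strictly decreases the loss
  z1 <- rbind(c(1, 0, 0), c(0.5, 0, 0), 0, 0)
  z2 <- rbind(c(1, 0, 0), c(0.9, 0, 0), 0, 0)
  expect_lt(graph_loss(z2, g), graph_loss(z1, g))
})

test_that("InfoNCE reduces to ln(3) at infinite temperature with T = 2", {
  set.seed(12)
  z <- matrix(rnorm(4 * 5), 4, 5)
  pairs <- structure(list(pairs = list(rna = rbind(c(1, 2), c(3, 4))),
                          n_pairs = 2, tau = 1e12), class = "PairSet")
  expect_equal(info_nce_loss(z, pairs), log(3), tolerance = 1e-6)
})

test_that("InfoNCE equals the literal nested-loop oracle", {
  set.seed(23)
  for (Tn in c(2, 3, 4, 6)) {
    z <- matrix(rnorm(2 * Tn * 4), 2 * Tn, 4)
    idx <- matrix(seq_len(2 * Tn), ncol = 2, byrow = TRUE)
    tau <- runif(1, 0.2, 2)
    pairs <- structure(list(pairs = list(rna = idx), n_pairs = Tn, tau = tau),
                       class = "PairSet")
    expect_equal(info_nce_loss(z, pairs),
                 nce_loop_oracle(z[idx[, 1], , drop = FALSE],
                                 z[idx[, 2], , drop = FALSE], tau),
                 tolerance = 1e-10)
  }
  # two modalities sum
  z <- matrix(rnorm(8 * 3), 8, 3)
  i1 <- rbind(c(1, 2), c(3, 4)); i2 <- rbind(c(5, 6), c(7, 8))
  pairs <- structure(list(pairs = list(a = i1, b = i2), n_pairs = 2, tau = 0.5),
                     class = "PairSet")
  expect_equal(info_nce_loss(z, pairs),
               nce_loop_oracle(z[i1[, 1], ], z[i1[, 2], ], 0.5) +
                 nce_loop_oracle(z[i2[, 1], ], z[i2[, 2], ], 0.5),
               tolerance = 1e-10)
  short <- structure(list(pairs = list(rna = rbind(c(1, 2))), n_pairs = 1,
                          tau = 0.5), class = "PairSet")
  expect_error(info_nce_loss(z, short), "2 pairs")
})

test_that("aligning a positive pair lowers its InfoNCE contribution", {
  set.seed(3)
  z <- matrix(rnorm(6 * 4), 6, 4)
  idx <- rbind(c(1, 2), c(3, 4), c(5, 6))
  pr <- function(zz) info_nce_loss(
    zz, structure(list(pairs = list(rna = idx), n_pairs = 3, tau = 0.5),
                  class = "PairSet"))
  before <- pr(z)
  z[2, ] <- z[1, ] * 2   # collinear positive pair
  expect_lt(pr(z), before)
})

test_that("triplet loss is the mean hinge of distance gaps", {
  z <- rbind(c(0, 0), c(0, 0), c(2, 0))
  ts <- structure(list(triplets = cbind(1, 2, 3), n_triplets = 1, margin = 1),
                  class = "TripletSet")
  expect_equal(triplet_loss(z, ts), 0)

  z2 <- rbind(c(0, 0), c(1, 0), c(0, 1))   # d(a,p) = d(a,n) = 1
  ts2 <- structure(list(triplets = cbind(1, 2, 3), n_triplets = 1, margin = 0.5),
                   class = "TripletSet")
  expect_equal(triplet_loss(z2, ts2), 0.5)

  z3 <- rbind(c(0, 0), c(0, 0), c(2, 0), c(0, 0), c(1, 0), c(0, 1))
  ts3 <- structure(list(triplets = rbind(c(1, 2, 3), c(4, 5, 6)),
                        n_triplets = 2, margin = c(1, 0.5)[1]), class = "TripletSet")
  ts3$margin <- 1
  # contributions: max(0-2+1,0)=0 and max(1-1+1,0)=1 -> mean 0.5
  expect_equal(triplet_loss(z3, ts3), 0.5)
})

test_that("total loss is the weighted sum of components", {
  comp <- list(recon = 1, kl = 2, graph = 3, contrastive = 4, triplet = 5)
  expect_equal(total_loss(comp, loss_weights(1, 1, 1, 1, 1)), 15)
  expect_equal(total_loss(comp, loss_weights(0, 0, 0, 0, 0)), 0)
  expect_equal(total_loss(list(recon = 3, kl = 4, graph = 0, contrastive = 0,
                               triplet = 0), loss_weights(2, 1, 0, 0, 0)), 10)
  expect_error(loss_weights(-1, 1, 1, 1, 1), "non-negative")
})

test_that("losses are invariant to coherent cell permutation", {
  set.seed(41)
  n <- 12
  z <- matrix(rnorm(n * 4), n, 4)
  edges <- cbind(c(1, 3, 5), c(2, 4, 6))
  g <- make_graph(edges, n)
  pairs <- structure(list(pairs = list(rna = rbind(c(1, 2), c(3, 4), c(5, 6))),
                          n_pairs = 3, tau = 0.7), class = "PairSet")
  trip <- structure(list(triplets = rbind(c(1, 2, 7), c(3, 4, 8)),
                         n_triplets = 2, margin = 1), class = "TripletSet")
  perm <- sample(n)
  inv <- order(perm)   # position of original cell i in the permuted matrix
  zp <- z[perm, , drop = FALSE]
  remap <- function(m) matrix(inv[m], nrow = nrow(m))
  gp <- make_graph(remap(edges), n)
  pp <- structure(list(pairs = list(rna = remap(pairs$pairs$rna)),
                       n_pairs = 3, tau = 0.7), class = "PairSet")
  tp <- structure(list(triplets = remap(trip$triplets), n_triplets = 2,
                       margin = 1), class = "TripletSet")
  expect_equal(graph_loss(zp, gp), graph_loss(z, g))
  expect_equal(info_nce_loss(zp, pp), info_nce_loss(z, pairs))
  expect_equal(triplet_loss(zp, tp), triplet_loss(z, trip))
})
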