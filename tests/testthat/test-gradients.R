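# The training loop differentiates the full objective by hand; these tests
# pin the analytic gradients to central finite differences and the forward
# pass to the standalone loss functions.

grad_fixture <- function(seed = 19) {
  set.seed(seed)
  n <- 10
  params <- init_model_params(c(rna = 6, adt = 4), latent_dim = 3, hidden = 5,
                              seed = seed)
  views <- list(rna = matrix(rnorm(n * 6), n, 6),
                adt = matrix(rnorm(n * 4), n, 4))
  mask <- cbind(rna = rep(TRUE, n), adt = c(rep(TRUE, 7), rep(FALSE, 3)))
  cells <- 1:n
  eps <- matrix(rnorm(n * 3), n, 3)
  edges <- list(rna = rbind(c(1, 2), c(2, 1), c(3, 5), c(5, 3)),
                adt = rbind(c(4, 6), c(6, 4)))
  pairs <- list(rna = rbind(c(1, 2), c(3, 5), c(2, 1)),
                adt = rbind(c(4, 6), c(6, 4)))
  triplets <- rbind(c(1, 2, 9), c(3, 5, 10), c(2, 1, 8))
  weights <- loss_weights(1, 0.5, 2, 1.5, 3, extensive = FALSE)
  list(params = params, views = views, mask = mask, cells = cells, eps = eps,
       edges = edges, pairs = pairs, triplets = triplets, weights = weights,
       tau = 0.7, margin = 1.2, scale = 2.5, n_total = 25)
}

run_engine <- function(fx, params = fx$params, compute_grad = TRUE) {
  scmosaic:::vae_batch_grad(params, fx$views, fx$mask, fx$cells, fx$eps,
                            fx$edges, fx$pairs, fx$triplets, fx$weights,
                            fx$tau, fx$margin, fx$scale, fx$n_total,
                            compute_grad = compute_grad)
}

test_that("engine components equal the standalone loss functions", {
  fx <- grad_fixture()
  res <- run_engine(fx)
  z <- res$z

  # reconstruction via the public encode/decode path on the same z
  recon <- 0
  for (m in c("rna", "adt")) {
    avail <- which(fx$mask[, m])
    xh <- decode_modality(z[avail, , drop = FALSE], fx$params, m)
    recon <- recon + recon_loss(fx$views[[m]][avail, , drop = FALSE], xh)
  }
  expect_equal(res$components$recon, fx$scale * recon)

  # fused posterior via the public per-cell PoE path
  kl_ref <- 0
  posts <- lapply(c("rna", "adt"), function(m) {
    avail <- which(fx$mask[, m])
    list(m = m, avail = avail,
         post = encode_modality(fx$views[[m]][avail, , drop = FALSE],
                                fx$params, m))
  })
  for (i in seq_len(10)) {
    experts <- list()
    for (p in posts) {
      r <- match(i, p$avail)
      if (!is.na(r))
        experts <- c(experts, list(list(mean = p$post$mean[r, ],
                                        var = p$post$var[r, ])))
    }
    fused <- poe_combine(experts, latent_dim = 3)
    expect_equal(res$mu[i, ], fused$mean)
    kl_ref <- kl_ref + kl_loss(fused)
  }
  expect_equal(res$components$kl, fx$scale * kl_ref)

  und <- function(e) e[e[, 1] < e[, 2], , drop = FALSE]
  gref <- list(adjacency = lapply(fx$edges, function(e) {
    u <- und(e)
    Matrix::sparseMatrix(i = c(u[, 1], u[, 2]), j = c(u[, 2], u[, 1]), x = 1,
                         dims = c(10, 10))
  }), k = 1)
  expect_equal(res$components$graph,
               fx$scale * graph_loss(z, gref, n_total = fx$n_total))

  pset <- structure(list(pairs = fx$pairs, n_pairs = 3, tau = fx$tau),
                    class = "PairSet")
  expect_equal(res$components$contrastive, info_nce_loss(z, pset))

  tset <- structure(list(triplets = fx$triplets, n_triplets = 3,
                         margin = fx$margin), class = "TripletSet")
  expect_equal(res$components$triplet, triplet_loss(z, tset))

  expect_equal(res$total, total_loss(res$components, fx$weights))
})

test_that("analytic gradients match central finite differences", {
  fx <- grad_fixture()
  res <- run_engine(fx)
  h <- 1e-5
  set.seed(91)
  for (m in c("rna", "adt")) for (part in c("enc", "dec")) {
    for (nm in names(fx$params$modalities[[m]][[part]])) {
      tensor <- fx$params$modalities[[m]][[part]][[nm]]
      picks <- sample(length(tensor), min(6, length(tensor)))
      for (k in picks) {
        pp <- fx$params
        pp$modalities[[m]][[part]][[nm]][k] <- tensor[k] + h
        up <- run_engine(fx, pp, compute_grad = FALSE)$total
        pp$modalities[[m]][[part]][[nm]][k] <- tensor[k] - h
        dn <- run_engine(fx, pp, compute_grad = FALSE)$total
        fd <- (up - dn) / (2 * h)
        an <- res$grads[[m]][[part]][[nm]][k]
        expect_equal(an, fd, tolerance = 1e-4,
                     label = sprintf("grad %s$%s$%s[%d]", m, part, nm, k))
      }
    }
  }
})

test_that("gradients vanish for a modality absent from the batch", {
  fx <- grad_fixture()
  fx$mask[, "adt"] <- FALSE
  fx$edges$adt <- NULL
  fx$pairs$adt <- NULL
  res <- run_engine(fx)
  flat <- unlist(res$grads$adt)
  expect_true(all(flat == 0))
})
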