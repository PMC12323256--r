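# Exact analytic gradients for one mini-batch forward/backward pass.
# Everything is plain dense matrix algebra; correctness is pinned down by
# finite-difference tests rather than an autodiff framework.

# Scatter-add rows of `contrib` into an n x d matrix at (possibly repeated)
# row indices `idx`.
scatter_add <- function(acc, idx, contrib) {
  rs <- rowsum(contrib, group = idx)
  rows <- as.integer(rownames(rs))
  acc[rows, ] <- acc[rows, , drop = FALSE] + rs
  acc
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like)
  else if (is.matrix(p)) array(0, dim(p))
  else numeric(length(p))
}

# One mini-batch forward + backward.
#
# views:   named list of full (N x p_m) view matrices (NA rows for masked)
# mask:    N x M availability
# cells:   global indices of the mini-batch (length nB)
# eps:     nB x latent_dim pre-drawn standard normal noise
# edges:   named list of ordered local edge pairs (2-col matrices) per
#          modality, indices into `cells`
# pairs:   named list of local T x 2 pair matrices (or NULL to skip)
# triplets: local H x 3 matrix or NULL
# scale:   N / nB, applied to recon/kl/graph so full-data weights keep
#          their meaning
# n_total: full dataset size N (graph-loss denominator)
vae_batch_grad <- function(params, views, mask, cells, eps, edges,
                           pairs, triplets, weights, tau, margin,
                           scale, n_total, compute_grad = TRUE) {
  nB <- length(cells)
  d <- params$latent_dim
  mods <- names(params$modalities)

  # ---- forward: encoders -------------------------------------------------
  enc_cache <- list()
  means <- list(); vars <- list(); contrib <- list()
  for (m in mods) {
    avail <- which(mask[cells, m])
    mu_full <- matrix(0, nB, d); var_full <- matrix(1, nB, d)
    cm <- rep(0, nB)
    if (length(avail) > 0) {
      enc <- params$modalities[[m]]$enc
      x <- views[[m]][cells[avail], , drop = FALSE]
      hpre <- add_bias(x %*% enc$W1, enc$b1)
      h <- relu(hpre)
      mu <- add_bias(h %*% enc$Wmu, enc$bmu)
      spre <- add_bias(h %*% enc$Ws, enc$bs)
      v <- softplus(spre) + VAR_FLOOR
      mu_full[avail, ] <- mu; var_full[avail, ] <- v
      cm[avail] <- 1
      enc_cache[[m]] <- list(avail = avail, x = x, hpre = hpre, h = h,
                             spre = spre, mu = mu, v = v)
    }
    means[[m]] <- mu_full; vars[[m]] <- var_full; contrib[[m]] <- cm
  }

  fused <- poe_fuse_matrix(means, vars, contrib)
  mu_f <- fused$mean; nu_f <- fused$var; prec <- fused$prec
  z <- mu_f + sqrt(nu_f) * eps

  # ---- forward: decoders + losses ---------------------------------------
  recon <- 0
  dec_cache <- list()
  for (m in mods) {
    ec <- enc_cache[[m]]
    if (is.null(ec)) next
    dec <- params$modalities[[m]]$dec
    zm <- z[ec$avail, , drop = FALSE]
    hdpre <- add_bias(zm %*% dec$W1, dec$b1)
    hd <- relu(hdpre)
    xhat <- add_bias(hd %*% dec$W2, dec$b2)
    recon <- recon + sum((ec$x - xhat)^2)
    dec_cache[[m]] <- list(zm = zm, hdpre = hdpre, hd = hd, xhat = xhat)
  }

  kl <- 0.5 * sum(nu_f + mu_f^2 - 1 - log(nu_f))

  graph <- 0
  graph_cache <- list()
  for (m in mods) {
    e <- edges[[m]]
    if (is.null(e) || nrow(e) == 0) next
    s <- rowSums(z[e[, 1], , drop = FALSE] * z[e[, 2], , drop = FALSE])
    graph <- graph - sum(log_sigmoid(s))
    graph_cache[[m]] <- list(e = e, s = s)
  }
  graph <- graph / n_total

  con <- 0
  con_cache <- list()
  for (m in mods) {
    p <- pairs[[m]]
    if (is.null(p) || nrow(p) < 2) next
    u <- z[p[, 1], , drop = FALSE]; v <- z[p[, 2], , drop = FALSE]
    nu_r <- sqrt(rowSums(u^2)); nv_r <- sqrt(rowSums(v^2))
    uh <- u / nu_r; vh <- v / nv_r
    S <- tcrossprod(uh, vh)
    Tn <- nrow(p)
    E <- exp(S / tau - max(S / tau))          # global shift cancels
    D <- rowSums(E) + colSums(E) - diag(E)
    con_m <- -(1 / Tn) * sum(diag(S) / tau - (log(D) + max(S / tau)))
    con <- con + con_m
    con_cache[[m]] <- list(p = p, uh = uh, vh = vh, nu_r = nu_r,
                           nv_r = nv_r, S = S, E = E, D = D, Tn = Tn)
  }

  tri <- 0
  tri_cache <- NULL
  if (!is.null(triplets) && nrow(triplets) > 0) {
    a <- z[triplets[, 1], , drop = FALSE]
    p_ <- z[triplets[, 2], , drop = FALSE]
    n_ <- z[triplets[, 3], , drop = FALSE]
    d_ap <- sqrt(rowSums((a - p_)^2)); d_an <- sqrt(rowSums((a - n_)^2))
    hinge <- d_ap - d_an + margin
    active <- hinge > 0
    tri <- mean(pmax(hinge, 0))
    tri_cache <- list(a = a, p = p_, n = n_, d_ap = d_ap, d_an = d_an,
                      active = active, H = nrow(triplets))
  }

  components <- list(recon = scale * recon, kl = scale * kl,
                     graph = scale * graph, contrastive = con, triplet = tri)
  nm <- c("recon", "kl", "graph", "contrastive", "triplet")
  total <- sum(unlist(components[nm]) * unlist(weights[nm]))  # may be non-finite
  # on divergence the caller reports which term went non-finite
  if (!compute_grad || !is.finite(total))
    return(list(components = components, total = total, z = z, mu = mu_f))

  # ---- backward ----------------------------------------------------------
  grads <- list()
  dZ <- matrix(0, nB, d)

  for (m in mods) {
    ec <- enc_cache[[m]]
    if (is.null(ec)) { grads[[m]] <- zeros_like(params$modalities[[m]]); next }
    dc <- dec_cache[[m]]
    dec <- params$modalities[[m]]$dec
    dxhat <- weights$recon * scale * 2 * (dc$xhat - ec$x)
    dW2 <- crossprod(dc$hd, dxhat); db2 <- colSums(dxhat)
    dhd <- tcrossprod(dxhat, dec$W2) * (dc$hdpre > 0)
    dW1d <- crossprod(dc$zm, dhd); db1d <- colSums(dhd)
    dZ[ec$avail, ] <- dZ[ec$avail, , drop = FALSE] + tcrossprod(dhd, dec$W1)
    grads[[m]] <- list(dec = list(W1 = dW1d, b1 = db1d, W2 = dW2, b2 = db2))
  }

  dMu <- weights$kl * scale * mu_f
  dNu <- weights$kl * scale * 0.5 * (1 - 1 / nu_f)

  for (m in names(graph_cache)) {
    gc_ <- graph_cache[[m]]
    g <- weights$graph * scale * (sigmoid(gc_$s) - 1) / n_total
    dZ <- scatter_add(dZ, gc_$e[, 1], g * z[gc_$e[, 2], , drop = FALSE])
    dZ <- scatter_add(dZ, gc_$e[, 2], g * z[gc_$e[, 1], , drop = FALSE])
  }

  for (m in names(con_cache)) {
    cc <- con_cache[[m]]
    w <- 1 / cc$D
    G <- cc$E * outer(w, w, `+`)
    diag(G) <- diag(cc$E) * w - 1
    G <- G * weights$contrastive / (cc$Tn * tau)
    GU <- (G %*% cc$vh - rowSums(G * cc$S) * cc$uh) / cc$nu_r
    GV <- (crossprod(G, cc$uh) - colSums(G * cc$S) * cc$vh) / cc$nv_r
    dZ <- scatter_add(dZ, cc$p[, 1], GU)
    dZ <- scatter_add(dZ, cc$p[, 2], GV)
  }

  if (!is.null(tri_cache)) {
    tc <- tri_cache
    act <- tc$active & tc$d_ap > 0 & tc$d_an > 0
    if (any(act)) {
      coef <- weights$triplet / tc$H
      uap <- (tc$a[act, , drop = FALSE] - tc$p[act, , drop = FALSE]) / tc$d_ap[act]
      uan <- (tc$a[act, , drop = FALSE] - tc$n[act, , drop = FALSE]) / tc$d_an[act]
      ta <- triplets[act, , drop = FALSE]
      dZ <- scatter_add(dZ, ta[, 1], coef * (uap - uan))
      dZ <- scatter_add(dZ, ta[, 2], -coef * uap)
      dZ <- scatter_add(dZ, ta[, 3], coef * uan)
    }
  }

  # reparameterization: z = mu + sqrt(nu) * eps
  dMu <- dMu + dZ
  dNu <- dNu + dZ * eps * 0.5 / sqrt(nu_f)

  # PoE: mu = Sw / prec, nu = 1 / prec
  Sw <- mu_f * prec
  dSw <- dMu / prec
  dPrec <- -(dMu * Sw + dNu) / prec^2

  for (m in mods) {
    ec <- enc_cache[[m]]
    if (is.null(ec)) next
    av <- ec$avail
    dmu_m <- dSw[av, , drop = FALSE] / ec$v
    dvar_m <- -dSw[av, , drop = FALSE] * ec$mu / ec$v^2 -
      dPrec[av, , drop = FALSE] / ec$v^2
    dspre <- dvar_m * sigmoid(ec$spre)
    enc <- params$modalities[[m]]$enc
    dWmu <- crossprod(ec$h, dmu_m); dbmu <- colSums(dmu_m)
    dWs <- crossprod(ec$h, dspre); dbs <- colSums(dspre)
    dh <- (tcrossprod(dmu_m, enc$Wmu) + tcrossprod(dspre, enc$Ws)) *
      (ec$hpre > 0)
    dW1 <- crossprod(ec$x, dh); db1 <- colSums(dh)
    grads[[m]]$enc <- list(W1 = dW1, b1 = db1, Wmu = dWmu, bmu = dbmu,
                           Ws = dWs, bs = dbs)
  }

  list(components = components, total = total, grads = grads, z = z, mu = mu_f)
}
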