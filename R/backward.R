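# Reverse-mode gradients through the full model, hand-derived layer by
# layer. Entry point: .emgnn_backward(model, fw, dlogits, ...) where `fw` is
# the cache returned by .emgnn_forward and `dlogits` the gradient of the
# scalar objective with respect to the (N x 2) logits. Computes, on demand,
# gradients with respect to the parameters (training), the input feature
# matrix (node-feature integrated gradients) and the meta-edge weights
# (meta-edge integrated gradients).

.zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

.emgnn_backward <- function(model, fw, dlogits, need_params = TRUE,
                            need_x = FALSE, need_w = FALSE) {
  cfg <- model$config
  p <- model$params
  conv <- cfg$conv_type
  ds <- fw$ds
  N <- length(ds$universe)
  ni <- ds$n_inst
  L2 <- cfg$f2_layers
  grads <- if (need_params) .zero_like(p) else NULL

  # ---- f3 ---------------------------------------------------------------
  Mout <- fw$f2_caches[[L2]]$Z[seq_len(N), , drop = FALSE]
  dA1d <- dlogits %*% t(p$f3$W2)
  if (need_params) {
    grads$f3$W2 <- crossprod(fw$A1d, dlogits)
    grads$f3$b2 <- colSums(dlogits)
  }
  dA1 <- if (is.null(fw$mask3)) dA1d else dA1d * fw$mask3
  dZ1 <- dA1 * (fw$Z1 > 0)
  if (need_params) {
    grads$f3$W1 <- crossprod(Mout, dZ1)
    grads$f3$b1 <- colSums(dZ1)
  }
  dM <- dZ1 %*% t(p$f3$W1)

  # ---- f2 (star graphs) -------------------------------------------------
  dT <- rbind(dM, matrix(0, ni, ncol(dM)))
  dw <- if (need_w) rep(0, ni) else NULL
  coef <- 1 / sqrt(2 * (1 + ds$k_meta[ds$inst_gene]))
  for (l in rev(seq_len(L2))) {
    st <- fw$f2_caches[[l]]
    if (l < L2) {
      dA <- if (is.null(st$mask)) dT else dT * st$mask
      dZ <- dA * (st$Z > 0)
    } else {
      dZ <- dT
    }
    if (conv == "gcn") {
      if (need_params) {
        grads$f2[[l]]$W <- grads$f2[[l]]$W + crossprod(st$P, dZ)
        grads$f2[[l]]$b <- grads$f2[[l]]$b + colSums(dZ)
      }
      dP <- dZ %*% t(p$f2[[l]]$W)
      if (need_w) {
        ii <- N + seq_len(ni)
        t1 <- rowSums(dP[ds$inst_gene, , drop = FALSE] *
                        st$Tin[ii, , drop = FALSE])
        t2 <- rowSums(dP[ii, , drop = FALSE] *
                        st$Tin[ds$inst_gene, , drop = FALSE])
        dw <- dw + coef * (t1 + t2)
      }
      dT <- as.matrix(fw$S_star %*% dP)   # S_star is symmetric
    } else {
      bw <- .gat_backward(st$gat, ds$gat_star, p$f2[[l]], dZ,
                          cfg$gat_heads, cfg$leaky_slope, need_w = need_w)
      if (need_params) {
        grads$f2[[l]] <- Map(`+`, grads$f2[[l]], bw$grads[names(grads$f2[[l]])])
      }
      if (need_w) dw <- dw + bw$dw
      dT <- bw$dH
    }
  }
  dM0pre <- dT[seq_len(N), , drop = FALSE]
  dHinst <- dT[N + seq_len(ni), , drop = FALSE]

  # ---- meta projection ---------------------------------------------------
  if (need_params) {
    grads$proj$W <- crossprod(fw$X, dM0pre)
    grads$proj$b <- colSums(dM0pre)
  }
  dX_proj <- if (need_x) dM0pre %*% t(p$proj$W) else NULL

  # ---- f1 per layer graph -------------------------------------------------
  dX <- if (need_x) dX_proj else NULL
  offsets <- c(0L, cumsum(vapply(ds$node_idx, length, 0L)))
  for (i in seq_along(ds$layers)) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    if (offsets[i + 1L] == offsets[i]) next
    dH <- dHinst[rows, , drop = FALSE]
    for (l in rev(seq_len(cfg$f1_layers))) {
      st <- fw$layer_caches[[i]][[l]]
      dA <- if (is.null(st$mask)) dH else dH * st$mask
      dZ <- dA * (st$Z > 0)
      if (conv == "gcn") {
        if (need_params) {
          grads$f1[[l]]$W <- grads$f1[[l]]$W + crossprod(st$P, dZ)
          grads$f1[[l]]$b <- grads$f1[[l]]$b + colSums(dZ)
        }
        dP <- dZ %*% t(p$f1[[l]]$W)
        dH <- as.matrix(ds$Ahat[[i]] %*% dP)
      } else {
        bw <- .gat_backward(st$gat, ds$gat_f1[[i]], p$f1[[l]], dZ,
                            cfg$gat_heads, cfg$leaky_slope)
        if (need_params) {
          grads$f1[[l]] <- Map(`+`, grads$f1[[l]],
                               bw$grads[names(grads$f1[[l]])])
        }
        dH <- bw$dH
      }
    }
    if (need_x) dX[ds$node_idx[[i]], ] <- dX[ds$node_idx[[i]], ] + dH
  }

  list(params = grads, dX = dX, dX_proj = dX_proj,
       dw = if (is.null(dw)) NULL else unname(dw))
}

# Gradient of the positive-class probability of gene j w.r.t. the logits.
.dlogits_for_gene <- function(fw, j) {
  d <- matrix(0, nrow(fw$logits), 2L)
  p1 <- fw$prob[j, 1L]; p2 <- fw$prob[j, 2L]
  d[j, ] <- c(-p1 * p2, p2 * (1 - p2))
  d
}

# Fast input-feature gradient of gene j's positive-class probability for GCN
# models in evaluation mode. Exploits that the adjoint's support stays inside
# gene j's star through f3/f2 (the star operator couples a meta-node only
# with its own instances), so only the f1 stage needs whole-graph work.
# Exactly equals the need_x = TRUE path of .emgnn_backward.
.x_grad_single_gcn <- function(model, fw, j) {
  p <- model$params
  cfg <- model$config
  ds <- fw$ds
  N <- length(ds$universe)
  inst <- which(ds$inst_gene == j)
  k <- length(inst)
  idx <- c(j, N + inst)                     # star rows in the block layout
  p1 <- fw$prob[j, 1L]; p2 <- fw$prob[j, 2L]
  dlog <- c(-p1 * p2, p2 * (1 - p2))
  da1 <- as.vector(p$f3$W2 %*% dlog)
  dz1 <- da1 * (fw$Z1[j, ] > 0)
  dm <- as.vector(p$f3$W1 %*% dz1)
  dT <- rbind(dm, matrix(0, k, length(dm)))
  c_self <- 1 / (1 + k)
  c_e <- 1 / sqrt(2 * (1 + k))
  wj <- fw$w[inst]
  Sj <- matrix(0, k + 1L, k + 1L)
  Sj[1L, 1L] <- c_self
  if (k) {
    Sj[1L, 1L + seq_len(k)] <- c_e * wj
    Sj[1L + seq_len(k), 1L] <- c_e * wj
    diag(Sj)[1L + seq_len(k)] <- 0.5
  }
  for (l in rev(seq_len(cfg$f2_layers))) {
    st <- fw$f2_caches[[l]]
    dZ <- if (l < cfg$f2_layers) dT * (st$Z[idx, , drop = FALSE] > 0) else dT
    dP <- dZ %*% t(p$f2[[l]]$W)
    dT <- Sj %*% dP
  }
  dX <- matrix(0, N, ncol(fw$X))
  dX[j, ] <- as.vector(p$proj$W %*% dT[1L, ])
  dx_meta <- dX[j, ]
  offsets <- c(0L, cumsum(vapply(ds$node_idx, length, 0L)))
  for (t in seq_len(k)) {
    i <- ds$inst_layer[inst[t]]
    pos <- inst[t] - offsets[i]
    dH <- matrix(0, length(ds$node_idx[[i]]), ncol(dT))
    dH[pos, ] <- dT[1L + t, ]
    for (l in rev(seq_len(cfg$f1_layers))) {
      st <- fw$layer_caches[[i]][[l]]
      dZ <- dH * (st$Z > 0)
      dP <- dZ %*% t(p$f1[[l]]$W)
      dH <- as.matrix(ds$Ahat[[i]] %*% dP)
    }
    dX[ds$node_idx[[i]], ] <- dX[ds$node_idx[[i]], ] + dH
  }
  list(dX = dX, dX_meta_row = dx_meta)
}
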