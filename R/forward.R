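# Core forward computation of the multilayer GNN.
#
# Stage 1 (f1): the shared GNN runs independently on every layer graph,
# producing per-instance states. Stage 2 (f2): each gene's meta-node --
# initialized by a learned projection of the gene's raw features -- exchanges
# messages with that gene's layer instances over its star graph; the star
# graphs of all genes are processed jointly as one block graph whose first N
# node slots are meta-nodes and remaining slots the layer-major instances.
# Meta-edges carry continuous weights `w` (all 1 in ordinary operation;
# interpolated during integrated-gradients edge attribution), which scale the
# messages across the meta-edge but not the normalization/attention
# coefficients. Stage 3 (f3): an MLP with a two-class softmax head maps the
# meta-node state to the positive-class probability.

.relu <- function(x) (x > 0) * x

# fast row-recycled bias addition (column-major layout matches rep(each = n))
.addb <- function(Z, b) Z + rep(b, each = nrow(Z))

.dropout_mask <- function(dim, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(prod(dim)) >= rate) / (1 - rate), dim[1L], dim[2L])
}

# Star-graph propagation operator over c(meta nodes, instance nodes) with
# GCN normalization from the *binary* star structure; meta-edge messages are
# scaled by w. d_hat(meta_j) = 1 + k_j, d_hat(instance) = 2.
.star_operator <- function(ds, w) {
  N <- length(ds$universe)
  ni <- ds$n_inst
  coef <- 1 / sqrt(2 * (1 + ds$k_meta[ds$inst_gene]))
  cw <- coef * w
  Matrix::sparseMatrix(
    i = c(ds$inst_gene, N + seq_len(ni), seq_len(N), N + seq_len(ni)),
    j = c(N + seq_len(ni), ds$inst_gene, seq_len(N), N + seq_len(ni)),
    x = c(cw, cw, 1 / (1 + ds$k_meta), rep(0.5, ni)),
    dims = c(N + ni, N + ni))
}

# Lazily computed GAT edge structures (only needed for conv_type = "gat").
.prepare_structs <- function(ds, model) {
  if (model$config$conv_type != "gat" || !is.null(ds$gat_f1)) return(ds)
  ds$gat_f1 <- lapply(seq_along(ds$layers), function(i) {
    .gat_struct(length(ds$layers[[i]]$nodes), ds$edge_idx[[i]])
  })
  N <- length(ds$universe)
  star_edges <- cbind(ds$inst_gene, N + seq_len(ds$n_inst))
  ds$gat_star <- .gat_struct(N + ds$n_inst, star_edges,
                             msg_edge = seq_len(ds$n_inst))
  ds
}

.gat_forward <- function(H, struct, params, heads, slope, msg_w = NULL) {
  G <- H %*% params$W
  d_out <- ncol(G)
  hd <- d_out %/% heads
  src <- struct$src; dst <- struct$dst
  we <- rep(1, length(src))
  if (!is.null(msg_w) && !is.null(struct$msg_edge)) {
    has <- !is.na(struct$msg_edge)
    we[has] <- msg_w[struct$msg_edge[has]]
  }
  out <- matrix(0, struct$n, d_out)
  alpha <- z <- matrix(0, length(src), heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * hd + seq_len(hd)
    Gh <- G[, cols, drop = FALSE]
    s <- as.vector(Gh %*% params$a_dst[, h])
    t_ <- as.vector(Gh %*% params$a_src[, h])
    zh <- s[dst] + t_[src]
    pre <- ifelse(zh > 0, zh, slope * zh)
    mx <- vapply(struct$groups, function(ix) max(pre[ix]), 0)
    ex <- exp(pre - mx[dst])
    den <- as.vector(rowsum(ex, dst))
    ah <- ex / den[dst]
    out[, cols] <- rowsum((ah * we) * Gh[src, , drop = FALSE], dst)
    alpha[, h] <- ah
    z[, h] <- zh
  }
  out <- .addb(out, params$b)
  list(out = out, G = G, alpha = alpha, z = z, we = we, H = H)
}

.gat_backward <- function(cache, struct, params, dOut, heads, slope,
                          need_w = FALSE) {
  G <- cache$G
  d_out <- ncol(G)
  hd <- d_out %/% heads
  src <- struct$src; dst <- struct$dst
  dG <- matrix(0, nrow(G), d_out)
  da_dst <- da_src <- matrix(0, hd, heads)
  dw_msg <- NULL
  if (need_w && !is.null(struct$msg_edge)) dw_msg <- numeric(0L)
  dmsg_acc <- rep(0, length(src))
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * hd + seq_len(hd)
    Gh <- G[, cols, drop = FALSE]
    dOh <- dOut[, cols, drop = FALSE]
    ah <- cache$alpha[, h]
    dot <- rowSums(dOh[dst, , drop = FALSE] * Gh[src, , drop = FALSE])
    dalpha <- dot * cache$we
    dmsg_acc <- dmsg_acc + ah * dot
    dG <- dG + .add_cols(matrix(0, nrow(G), d_out), cols,
                         rowsum((ah * cache$we) * dOh[dst, , drop = FALSE], src))
    ssum <- as.vector(rowsum(ah * dalpha, dst))
    dz_soft <- ah * (dalpha - ssum[dst])
    zh <- cache$z[, h]
    dzh <- dz_soft * ifelse(zh > 0, 1, slope)
    ds_ <- as.vector(rowsum(dzh, dst))
    dt_ <- as.vector(rowsum(dzh, src))
    dG[, cols] <- dG[, cols] + outer(ds_, params$a_dst[, h]) +
      outer(dt_, params$a_src[, h])
    da_dst[, h] <- as.vector(crossprod(Gh, ds_))
    da_src[, h] <- as.vector(crossprod(Gh, dt_))
  }
  grads <- list(W = crossprod(cache$H, dG), b = colSums(dOut),
                a_dst = da_dst, a_src = da_src)
  out <- list(dH = dG %*% t(params$W), grads = grads)
  if (need_w && !is.null(struct$msg_edge)) {
    has <- which(!is.na(struct$msg_edge))
    out$dw <- as.vector(rowsum(dmsg_acc[has],
                               struct$msg_edge[has],
                               reorder = TRUE))
  }
  out
}

.add_cols <- function(M, cols, val) {
  M[, cols] <- M[, cols] + val
  M
}

# Full forward pass. Returns yhat plus every intermediate needed by
# .emgnn_backward. `w` is the meta-edge weight vector (length n_inst).
.emgnn_forward <- function(model, ds, X = ds$X, w = NULL, training = FALSE) {
  cfg <- model$config
  p <- model$params
  conv <- cfg$conv_type
  N <- length(ds$universe)
  if (is.null(w)) w <- rep(1, ds$n_inst)
  if (conv == "gat") ds <- .prepare_structs(ds, model)
  drop_rate <- if (training) cfg$dropout else 0

  # ---- stage 1: shared per-layer GNN -------------------------------------
  layer_caches <- vector("list", length(ds$layers))
  H_list <- vector("list", length(ds$layers))
  for (i in seq_along(ds$layers)) {
    H <- X[ds$node_idx[[i]], , drop = FALSE]
    steps <- vector("list", cfg$f1_layers)
    for (l in seq_len(cfg$f1_layers)) {
      st <- list(Hin = H)
      if (conv == "gcn") {
        st$P <- as.matrix(ds$Ahat[[i]] %*% H)
        Z <- st$P %*% p$f1[[l]]$W
        Z <- .addb(Z, p$f1[[l]]$b)
      } else {
        st$gat <- .gat_forward(H, ds$gat_f1[[i]], p$f1[[l]], cfg$gat_heads,
                               cfg$leaky_slope)
        Z <- st$gat$out
      }
      st$Z <- Z
      A <- .relu(Z)
      st$mask <- if (drop_rate > 0) .dropout_mask(dim(A), drop_rate) else NULL
      H <- if (is.null(st$mask)) A else A * st$mask
      steps[[l]] <- st
    }
    layer_caches[[i]] <- steps
    H_list[[i]] <- H
  }
  Hinst <- do.call(rbind, H_list)

  # ---- stage 2: meta-GNN over per-gene star graphs -----------------------
  M0pre <- .addb(X %*% p$proj$W, p$proj$b)
  T_ <- rbind(M0pre, Hinst)
  f2_caches <- vector("list", cfg$f2_layers)
  if (conv == "gcn") S_star <- .star_operator(ds, w)
  for (l in seq_len(cfg$f2_layers)) {
    st <- list(Tin = T_)
    if (conv == "gcn") {
      st$P <- as.matrix(S_star %*% T_)
      Z <- .addb(st$P %*% p$f2[[l]]$W, p$f2[[l]]$b)
    } else {
      st$gat <- .gat_forward(T_, ds$gat_star, p$f2[[l]], cfg$gat_heads,
                             cfg$leaky_slope, msg_w = w)
      Z <- st$gat$out
    }
    st$Z <- Z
    if (l < cfg$f2_layers) {        # ReLU + dropout except after last layer
      A <- .relu(Z)
      st$mask <- if (drop_rate > 0) .dropout_mask(dim(A), drop_rate) else NULL
      T_ <- if (is.null(st$mask)) A else A * st$mask
    } else {
      T_ <- Z
    }
    f2_caches[[l]] <- st
  }
  M <- T_[seq_len(N), , drop = FALSE]   # meta-node outputs

  # ---- stage 3: classifier MLP -------------------------------------------
  Z1 <- .addb(M %*% p$f3$W1, p$f3$b1)
  A1 <- .relu(Z1)
  mask3 <- if (drop_rate > 0) .dropout_mask(dim(A1), drop_rate) else NULL
  A1d <- if (is.null(mask3)) A1 else A1 * mask3
  logits <- .addb(A1d %*% p$f3$W2, p$f3$b2)
  mx <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - mx); e2 <- exp(logits[, 2L] - mx)
  prob <- e2 / (e1 + e2)

  list(yhat = setNames(prob, ds$universe), logits = logits,
       prob = cbind(1 - prob, prob),
       layer_caches = layer_caches, f2_caches = f2_caches,
       Hinst = Hinst, M0pre = M0pre, X = X, w = w,
       Z1 = Z1, A1d = A1d, mask3 = mask3,
       S_star = if (conv == "gcn") S_star else NULL, ds = ds)
}

#' Run the model forward and return predicted probabilities
#'
#' Deterministic evaluation-mode forward pass (dropout off).
#'
#' @param model An [emgnn_model()].
#' @param dataset An `emgnn_dataset` whose feature dimension matches the
#'   model.
#' @return Named numeric vector of positive-class probabilities, one per
#'   universe gene.
#' @export
emgnn_forward <- function(model, dataset) {
  stopifnot(inherits(model, "emgnn_model"), inherits(dataset, "emgnn_dataset"))
  if (ncol(dataset$X) != model$d_in) {
    .stopf("dataset has %d features but model expects %d",
           ncol(dataset$X), model$d_in)
  }
  .emgnn_forward(model, dataset)$yhat
}

#' @export
predict.emgnn_model <- function(object, dataset, ...) {
  yhat <- emgnn_forward(object, dataset)
  lab <- rep(NA_integer_, length(yhat))
  if (!is.null(dataset$labels)) {
    lab[names(yhat) %in% dataset$labels$positives] <- 1L
    lab[names(yhat) %in% dataset$labels$negatives] <- 0L
  }
  data.frame(gene = names(yhat), yhat = as.numeric(yhat), label = lab,
             stringsAsFactors = FALSE)
}
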