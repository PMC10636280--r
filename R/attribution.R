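#' Integrated gradients of a generic scalar function
#'
#' Midpoint Riemann approximation of the path integral of gradients from a
#' baseline to the input:
#' `(x_i - xhat_i) * (1/steps) * sum_s dF(xhat + a_s (x - xhat)) / dx_i`
#' with `a_s = (s - 1/2) / steps`. For a linear `F` the result is exact for
#' any number of steps.
#'
#' @param grad_fn Function taking an input like `x` and returning the
#'   gradient of the scalar objective at that point (same shape as `x`).
#' @param x Input (numeric vector or matrix).
#' @param baseline Baseline input (default: all zeros).
#' @param steps Number of interpolation steps.
#' @return Attributions with the shape of `x`.
#' @export
integrated_gradients <- function(grad_fn, x, baseline = NULL, steps = 128L) {
  if (is.null(baseline)) baseline <- x * 0
  stopifnot(steps >= 1L)
  acc <- x * 0
  for (s in seq_len(steps)) {
    a <- (s - 0.5) / steps
    acc <- acc + grad_fn(baseline + a * (x - baseline))
  }
  (x - baseline) * acc / steps
}

# Genes within k hops of `gene` in any layer (BFS on each layer), plus the
# gene itself: the receptive field of the f1 stage.
.receptive_field <- function(ds, gene, k) {
  j <- match(gene, ds$universe)
  rf <- gene
  for (i in seq_along(ds$layers)) {
    nodes <- ds$layers[[i]]$nodes
    if (!gene %in% nodes) next
    e <- ds$edge_idx[[i]]
    adj <- vector("list", length(nodes))
    for (r in seq_len(nrow(e))) {
      adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
      adj[[e[r, 2L]]] <- c(adj[[e[r, 2L]]], e[r, 1L])
    }
    frontier <- match(gene, nodes)
    seen <- frontier
    for (hop in seq_len(k)) {
      if (!length(frontier)) break
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    rf <- c(rf, nodes[seen])
  }
  .csort(unique(rf))
}

#' Node-feature integrated gradients for one target gene
#'
#' Attributes the model's positive-class probability for the target gene's
#' meta-node to the input features, holding all edges fixed. The straight
#' path runs from an all-zero baseline to the actual feature matrix; the
#' integral is approximated by a midpoint Riemann sum. Attributions are
#' reported for every gene in the target's k-hop receptive field (k = number
#' of f1 message-passing layers) and, separately, for the target's own
#' meta-node input (the projection path).
#'
#' @param model A trained `emgnn_model`.
#' @param dataset An `emgnn_dataset`.
#' @param target_gene Gene identifier in the universe. A character vector of
#'   genes is also accepted; the interpolated forward passes are then shared
#'   across targets and a named list of results is returned.
#' @param steps Interpolation resolution (default 128).
#' @return Object of class `emgnn_attribution` with `target_gene`,
#'   `feature_matrix` (receptive-field genes x features; the total
#'   attribution flowing through each gene's feature vector),
#'   `meta_node_row` (the target's meta-node feature attributions),
#'   `completeness` (list: attribution sum, `f_x`, `f_baseline`), `steps`,
#'   `baseline = "zero"`. For multiple targets, a named list of such objects.
#' @export
ig_node_features <- function(model, dataset, target_gene, steps = 128L) {
  stopifnot(inherits(model, "emgnn_model"), inherits(dataset, "emgnn_dataset"))
  if (!isTRUE(model$trained)) {
    .stopf("model is untrained; train or load a checkpoint first")
  }
  jj <- match(target_gene, dataset$universe)
  if (anyNA(jj)) {
    .stopf("gene '%s' not in the universe", target_gene[which(is.na(jj))[1L]])
  }
  if (model$config$conv_type == "gat") {
    dataset <- .prepare_structs(dataset, model)
  }
  X <- dataset$X
  acc <- lapply(jj, function(j) X * 0)
  acc_meta <- lapply(jj, function(j) numeric(ncol(X)))
  gcn <- model$config$conv_type == "gcn"
  for (s in seq_len(steps)) {
    a <- (s - 0.5) / steps
    fw <- .emgnn_forward(model, dataset, X = a * X)
    for (t in seq_along(jj)) {
      if (gcn) {   # star-local fast path, identical to the generic backward
        bw <- .x_grad_single_gcn(model, fw, jj[t])
        acc[[t]] <- acc[[t]] + bw$dX
        acc_meta[[t]] <- acc_meta[[t]] + bw$dX_meta_row
      } else {
        bw <- .emgnn_backward(model, fw, .dlogits_for_gene(fw, jj[t]),
                              need_params = FALSE, need_x = TRUE)
        acc[[t]] <- acc[[t]] + bw$dX
        acc_meta[[t]] <- acc_meta[[t]] + bw$dX_proj[jj[t], ]
      }
    }
  }
  yh_x <- .emgnn_forward(model, dataset)$yhat
  yh_0 <- .emgnn_forward(model, dataset, X = X * 0)$yhat
  out <- lapply(seq_along(jj), function(t) {
    attr_full <- X * acc[[t]] / steps
    rf <- .receptive_field(dataset, target_gene[t], model$config$f1_layers)
    structure(list(
      target_gene = target_gene[t],
      feature_matrix = attr_full[rf, , drop = FALSE],
      meta_node_row = setNames(X[jj[t], ] * acc_meta[[t]] / steps,
                               colnames(X)),
      attribution_total = sum(attr_full),
      completeness = list(sum = sum(attr_full), f_x = yh_x[[jj[t]]],
                          f_baseline = yh_0[[jj[t]]]),
      steps = as.integer(steps), baseline = "zero",
      kind = "node_features"), class = "emgnn_attribution")
  })
  names(out) <- target_gene
  if (length(out) == 1L) out[[1L]] else out
}

#' Meta-edge integrated gradients for one target gene
#'
#' Attributes the prediction to the meta-edges (one per layer containing the
#' gene) by jointly interpolating all meta-edge weights from 0 to 1 while
#' holding node features fixed. Raw attributions are normalized per
#' meta-node to `[0,1]` by min-max scaling (for all-positive attributions
#' with a near-zero minimum this coincides with dividing by the maximum
#' value); the most important layer always scores exactly 1 whenever the
#' raw attributions are not all identical. A gene present in a single layer
#' scores 1 if its attribution is nonzero. Layers not containing the gene
#' have no meta-edge and report exactly 0.
#'
#' @inheritParams ig_node_features
#' @return Object of class `emgnn_attribution` with `meta_edge_attr` (named
#'   numeric over all layer ids, in `[0,1]`), `meta_edge_raw` (unnormalized,
#'   layers containing the gene only), `steps`. For multiple targets, a
#'   named list of such objects.
#' @details With GCN convolutions the computation uses an exact star-local
#'   fast path: the per-layer GNN outputs do not depend on the meta-edge
#'   weights, so after one stage-1 evaluation each target gene's prediction
#'   is a function of its own (K+1)-node star only. The generic whole-graph
#'   path (used for GAT) gives identical results.
#' @export
ig_meta_edges <- function(model, dataset, target_gene, steps = 128L) {
  stopifnot(inherits(model, "emgnn_model"), inherits(dataset, "emgnn_dataset"))
  if (!isTRUE(model$trained)) {
    .stopf("model is untrained; train or load a checkpoint first")
  }
  jj <- match(target_gene, dataset$universe)
  if (anyNA(jj)) {
    .stopf("gene '%s' not in the universe", target_gene[which(is.na(jj))[1L]])
  }
  if (model$config$conv_type == "gat") {
    dataset <- .prepare_structs(dataset, model)
    raw_list <- .ig_meta_edges_generic(model, dataset, jj, steps)
  } else {
    raw_list <- .ig_meta_edges_star(model, dataset, jj, steps)
  }
  out <- lapply(seq_along(jj), function(t) {
    inst_j <- which(dataset$inst_gene == jj[t])
    raw <- setNames(raw_list[[t]],
                    dataset$layer_ids[dataset$inst_layer[inst_j]])
    rng <- if (length(raw)) max(raw) - min(raw) else 0
    norm <- if (rng > 0) {
      (raw - min(raw)) / rng
    } else {
      # degenerate star: single meta-edge or identical attributions
      setNames(as.numeric(raw != 0), names(raw))
    }
    full <- setNames(rep(0, length(dataset$layer_ids)), dataset$layer_ids)
    full[names(norm)] <- norm
    structure(list(target_gene = target_gene[t],
                   meta_edge_attr = full, meta_edge_raw = raw,
                   steps = as.integer(steps), baseline = "zero-weight",
                   kind = "meta_edges"), class = "emgnn_attribution")
  })
  names(out) <- target_gene
  if (length(out) == 1L) out[[1L]] else out
}

# Whole-graph path: one forward + backward per interpolation step and
# target. Used for GAT (attention couples nodes beyond the star when
# normalization changes are involved in gradients).
.ig_meta_edges_generic <- function(model, dataset, jj, steps) {
  acc <- lapply(jj, function(j) rep(0, dataset$n_inst))
  for (s in seq_len(steps)) {
    a <- (s - 0.5) / steps
    fw <- .emgnn_forward(model, dataset, w = rep(a, dataset$n_inst))
    for (t in seq_along(jj)) {
      bw <- .emgnn_backward(model, fw, .dlogits_for_gene(fw, jj[t]),
                            need_params = FALSE, need_w = TRUE)
      acc[[t]] <- acc[[t]] + bw$dw
    }
  }
  lapply(seq_along(jj), function(t) {
    (acc[[t]] / steps)[which(dataset$inst_gene == jj[t])]
  })
}

# Exact star-local fast path for GCN: stage 1 and the meta projection are
# computed once; each (target, step) then runs f2 + f3 on the (k+1)-node
# star with dense arithmetic of size O((K+1) * hidden^2).
.ig_meta_edges_star <- function(model, dataset, jj, steps) {
  p <- model$params
  cfg <- model$config
  fw0 <- .emgnn_forward(model, dataset)   # w irrelevant for stage 1
  M0 <- fw0$M0pre
  Hinst <- fw0$Hinst
  lapply(jj, function(j) {
    inst <- which(dataset$inst_gene == j)
    k <- length(inst)
    if (!k) return(numeric(0))
    c_self <- 1 / (1 + k)
    c_e <- 1 / sqrt(2 * (1 + k))
    T0 <- rbind(M0[j, , drop = FALSE], Hinst[inst, , drop = FALSE])
    acc <- rep(0, k)
    for (s in seq_len(steps)) {
      a <- (s - 0.5) / steps
      w <- rep(a, k)
      Sj <- matrix(0, k + 1L, k + 1L)
      Sj[1L, 1L] <- c_self
      Sj[1L, 1L + seq_len(k)] <- c_e * w
      Sj[1L + seq_len(k), 1L] <- c_e * w
      diag(Sj)[1L + seq_len(k)] <- 0.5
      T_ <- T0
      caches <- vector("list", cfg$f2_layers)
      for (l in seq_len(cfg$f2_layers)) {
        st <- list(Tin = T_)
        st$P <- Sj %*% T_
        Z <- .addb(st$P %*% p$f2[[l]]$W, p$f2[[l]]$b)
        st$Z <- Z
        T_ <- if (l < cfg$f2_layers) .relu(Z) else Z
        caches[[l]] <- st
      }
      m <- T_[1L, ]
      z1 <- as.vector(m %*% p$f3$W1) + p$f3$b1
      a1 <- .relu(z1)
      logits <- as.vector(a1 %*% p$f3$W2) + p$f3$b2
      mx <- max(logits)
      e <- exp(logits - mx)
      p2 <- e[2L] / sum(e)
      dlog <- c(-(1 - p2) * p2, p2 * (1 - p2))
      da1 <- as.vector(p$f3$W2 %*% dlog)
      dz1 <- da1 * (z1 > 0)
      dm <- as.vector(p$f3$W1 %*% dz1)
      dT <- rbind(dm, matrix(0, k, length(dm)))
      for (l in rev(seq_len(cfg$f2_layers))) {
        st <- caches[[l]]
        dZ <- if (l < cfg$f2_layers) dT * (st$Z > 0) else dT
        dP <- dZ %*% t(p$f2[[l]]$W)
        ii <- 1L + seq_len(k)
        acc <- acc + c_e * (as.vector(st$Tin[ii, , drop = FALSE] %*% dP[1L, ]) +
                              rowSums(dP[ii, , drop = FALSE] *
                                        rep(st$Tin[1L, ], each = k)))
        dT <- Sj %*% dP
      }
    }
    acc / steps
  })
}

#' @export
print.emgnn_attribution <- function(x, ...) {
  cat(sprintf("<emgnn_attribution (%s) for gene '%s', steps=%d>\n",
              x$kind, x$target_gene, x$steps))
  invisible(x)
}

#' Rank neighboring genes by attribution importance
#'
#' Aggregates a node-feature attribution matrix to one importance per
#' neighboring gene: the (signed) maximum over that gene's feature
#' attributions. Genes whose attribution row is identically zero did not
#' contribute and are excluded. The target gene itself is excluded. Ties are
#' broken lexicographically.
#'
#' @param result An `emgnn_attribution` from [ig_node_features()].
#' @param absolute Use the maximum of absolute attributions instead of the
#'   signed maximum.
#' @return data.frame `gene`, `importance`, sorted by decreasing importance.
#' @export
aggregate_neighbor_importance <- function(result, absolute = FALSE) {
  stopifnot(inherits(result, "emgnn_attribution"),
            result$kind == "node_features")
  K <- result$feature_matrix
  K <- K[setdiff(rownames(K), result$target_gene), , drop = FALSE]
  if (!nrow(K)) .stopf("empty receptive field for '%s'", result$target_gene)
  nonzero <- rowSums(K != 0) > 0
  K <- K[nonzero, , drop = FALSE]
  if (!nrow(K)) {
    return(data.frame(gene = character(), importance = numeric(),
                      stringsAsFactors = FALSE))
  }
  imp <- if (absolute) apply(abs(K), 1L, max) else apply(K, 1L, max)
  ord <- order(-imp, rownames(K), method = "radix")
  data.frame(gene = rownames(K)[ord], importance = as.numeric(imp[ord]),
             stringsAsFactors = FALSE)
}
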