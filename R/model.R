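#' Model configuration
#'
#' Architecture hyperparameters of the multilayer GNN: a shared per-layer
#' GNN `f1` (default three layers, hidden 64), a meta-GNN `f2` over per-gene
#' star graphs (default one layer, hidden 64), and a one-hidden-layer MLP
#' classifier `f3`. `f1` parameters are shared across all input networks and
#' `f2` across all genes, so the trainable parameter count is independent of
#' the number of networks.
#'
#' @param conv_type `"gcn"` or `"gat"` (applies to both `f1` and `f2`).
#' @param f1_layers,f1_hidden Depth and width of the shared per-layer GNN.
#' @param f2_layers,f2_hidden Depth and width of the meta-GNN.
#' @param gat_heads Number of attention heads (GAT only; must divide the
#'   hidden widths).
#' @param dropout Dropout rate in `[0,1)`, applied to hidden states during
#'   training only.
#' @param leaky_slope Negative slope of the LeakyReLU in GAT attention.
#' @param seed Integer seed controlling parameter initialization and dropout.
#' @export
model_config <- function(conv_type = c("gcn", "gat"), f1_layers = 3L,
                         f1_hidden = 64L, f2_layers = 1L, f2_hidden = 64L,
                         gat_heads = 1L, dropout = 0.5, leaky_slope = 0.2,
                         seed = 1L) {
  conv_type <- match.arg(conv_type)
  stopifnot(f1_layers >= 1L, f2_layers >= 1L, f1_hidden >= 1L,
            f2_hidden >= 1L, dropout >= 0, dropout < 1, gat_heads >= 1L)
  if (conv_type == "gat" &&
      (f1_hidden %% gat_heads != 0L || f2_hidden %% gat_heads != 0L)) {
    .stopf("gat_heads must divide f1_hidden and f2_hidden")
  }
  structure(list(conv_type = conv_type, f1_layers = as.integer(f1_layers),
                 f1_hidden = as.integer(f1_hidden),
                 f2_layers = as.integer(f2_layers),
                 f2_hidden = as.integer(f2_hidden),
                 gat_heads = as.integer(gat_heads), dropout = dropout,
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "emgnn_config")
}

.glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

.init_gnn_layer <- function(d_in, d_out, conv, heads) {
  p <- list(W = .glorot(d_in, d_out), b = numeric(d_out))
  if (conv == "gat") {
    hd <- d_out %/% heads
    s <- sqrt(6 / (hd + 1))
    p$a_dst <- matrix(runif(hd * heads, -s, s), hd, heads) # center scores
    p$a_src <- matrix(runif(hd * heads, -s, s), hd, heads) # neighbor scores
  }
  p
}

#' Construct an (untrained) multilayer GNN model
#'
#' @param config A [model_config()].
#' @param d_in Input feature dimension.
#' @return Object of class `emgnn_model` with `config`, `d_in` and the
#'   parameter list: `f1` (shared GNN layers), `proj` (linear map
#'   `d_in -> f1_hidden` initializing meta-node states from raw gene
#'   features), `f2` (meta-GNN layers) and `f3` (classifier MLP,
#'   two-class softmax head).
#' @export
emgnn_model <- function(config, d_in) {
  stopifnot(inherits(config, "emgnn_config"), d_in >= 1L)
  set.seed(config$seed)
  conv <- config$conv_type
  h1 <- config$f1_hidden; h2 <- config$f2_hidden
  f1 <- vector("list", config$f1_layers)
  dims <- c(d_in, rep(h1, config$f1_layers))
  for (l in seq_len(config$f1_layers)) {
    f1[[l]] <- .init_gnn_layer(dims[l], dims[l + 1L], conv, config$gat_heads)
  }
  proj <- list(W = .glorot(d_in, h1), b = numeric(h1))
  f2 <- vector("list", config$f2_layers)
  dims2 <- c(h1, rep(h2, config$f2_layers))
  for (l in seq_len(config$f2_layers)) {
    f2[[l]] <- .init_gnn_layer(dims2[l], dims2[l + 1L], conv, config$gat_heads)
  }
  f3 <- list(W1 = .glorot(h2, h2), b1 = numeric(h2),
             W2 = .glorot(h2, 2L), b2 = numeric(2L))
  structure(list(config = config, d_in = as.integer(d_in),
                 params = list(f1 = f1, proj = proj, f2 = f2, f3 = f3)),
            class = "emgnn_model")
}

#' @export
print.emgnn_model <- function(x, ...) {
  cat(sprintf("<emgnn_model %s: f1 %dx%d, f2 %dx%d, d_in %d, %d parameters%s>\n",
              x$config$conv_type, x$config$f1_layers, x$config$f1_hidden,
              x$config$f2_layers, x$config$f2_hidden, x$d_in,
              count_parameters(x),
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

#' Count trainable parameters
#'
#' The count depends only on the configuration and input dimension, never on
#' the number of input networks (all per-layer GNN parameters are shared).
#'
#' @param model An `emgnn_model`.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

#' GCN aggregation step
#'
#' One graph-convolution step
#' `h'_u = W^T sum_{v in N(u) + {u}} h_v / sqrt(d_hat_v d_hat_u)` with
#' `d_hat_i = 1 + |N(i)|`. A degree-zero node keeps `h'_u = W^T h_u`.
#'
#' @param node_states Numeric `n x d_in` matrix of per-node states.
#' @param edges Two-column integer matrix of undirected edges (1-based row
#'   indices into `node_states`; no self-loops).
#' @param weight `d_in x d_out` weight matrix.
#' @return `n x d_out` matrix of updated states.
#' @export
gcn_aggregate <- function(node_states, edges, weight) {
  node_states <- as.matrix(node_states)
  if (nrow(weight) != ncol(node_states)) {
    .stopf("dimension mismatch: states have %d columns, weight %d rows",
           ncol(node_states), nrow(weight))
  }
  S <- normalized_adjacency(nrow(node_states), .as_edge_idx(edges))
  as.matrix(S %*% node_states %*% weight)
}

.as_edge_idx <- function(edges) {
  if (length(edges) == 0L) return(matrix(integer(), ncol = 2L))
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  edges
}

#' GAT aggregation step (single head)
#'
#' `h'_u = sum_{v in N(u) + {u}} alpha_{u,v} W h_v` with attention logits
#' `LeakyReLU(a^T [W h_u || W h_v])`, softmax-normalized over the closed
#' neighborhood of `u`. An isolated node gets `alpha_{u,u} = 1`.
#'
#' @inheritParams gcn_aggregate
#' @param attention_vector Numeric vector of length `2 * d_out`; the first
#'   half scores the central node, the second half the neighbor.
#' @param leaky_slope Negative slope of the LeakyReLU.
#' @param return_attention If `TRUE`, also return the per-edge attention
#'   coefficients.
#' @return `n x d_out` matrix, or a list with `states` and `attention`
#'   (data.frame `dst`, `src`, `alpha`) when `return_attention = TRUE`.
#' @export
gat_aggregate <- function(node_states, edges, weight, attention_vector,
                          leaky_slope = 0.2, return_attention = FALSE) {
  node_states <- as.matrix(node_states)
  if (nrow(weight) != ncol(node_states)) {
    .stopf("dimension mismatch: states have %d columns, weight %d rows",
           ncol(node_states), nrow(weight))
  }
  d_out <- ncol(weight)
  stopifnot(length(attention_vector) == 2L * d_out)
  n <- nrow(node_states)
  struct <- .gat_struct(n, .as_edge_idx(edges))
  params <- list(W = weight, b = numeric(d_out),
                 a_dst = matrix(attention_vector[seq_len(d_out)], d_out, 1L),
                 a_src = matrix(attention_vector[d_out + seq_len(d_out)],
                                d_out, 1L))
  fw <- .gat_forward(node_states, struct, params, heads = 1L,
                     slope = leaky_slope, msg_w = NULL)
  if (return_attention) {
    list(states = fw$out,
         attention = data.frame(dst = struct$dst, src = struct$src,
                                alpha = as.vector(fw$alpha)))
  } else {
    fw$out
  }
}

# Directed closed-neighborhood edge structure for attention layers:
# messages flow src -> dst; includes a self edge for every node.
.gat_struct <- function(n, edge_idx, msg_edge = NULL) {
  src <- c(edge_idx[, 1L], edge_idx[, 2L], seq_len(n))
  dst <- c(edge_idx[, 2L], edge_idx[, 1L], seq_len(n))
  ord <- order(dst, src)
  src <- src[ord]; dst <- dst[ord]
  groups <- split(seq_along(dst), dst)
  st <- list(n = n, src = src, dst = dst, groups = groups)
  if (!is.null(msg_edge)) {
    # index into the external message-weight vector (NA = fixed weight 1)
    st$msg_edge <- c(msg_edge, msg_edge, rep(NA_integer_, n))[ord]
  }
  st
}
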