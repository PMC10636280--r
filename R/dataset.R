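#' Assemble a multilayer dataset
#'
#' Bundles K interaction layers, the feature table and (optionally) labels
#' into the aligned structures the model consumes: the gene universe, the
#' universe-aligned feature matrix, per-layer node index vectors, sparse
#' symmetric-normalized adjacencies, and the meta-graph. Genes present in a
#' layer but lacking feature rows are dropped from that layer with a warning.
#'
#' @param layers List of [layer_graph()] objects (unique `layer_id`s).
#' @param features An `emgnn_features` table.
#' @param labels Optional [label_set()].
#' @return Object of class `emgnn_dataset`.
#' @export
multilayer_dataset <- function(layers, features, labels = NULL) {
  stopifnot(length(layers) >= 1L)
  ids <- vapply(layers, `[[`, "", "layer_id")
  if (anyDuplicated(ids)) .stopf("duplicate layer_id")
  universe <- build_gene_universe(layers, features)
  layers <- lapply(layers, function(g) {
    drop <- setdiff(g$nodes, universe)
    if (length(drop)) {
      .warnf("layer '%s': dropping %d gene(s) without feature rows",
             g$layer_id, length(drop))
      keep <- g$edges[, 1L] %in% universe & g$edges[, 2L] %in% universe
      g <- layer_graph(g$layer_id, g$edges[keep, , drop = FALSE],
                       confidence = g$confidence[keep],
                       nodes = intersect(g$nodes, universe))
    }
    g
  })
  X <- features$values[match(universe, features$genes), , drop = FALSE]
  rownames(X) <- universe
  ds <- structure(list(
    universe = universe,
    X = X,
    feature_names = features$feature_names,
    layers = layers,
    layer_ids = ids,
    labels = labels
  ), class = "emgnn_dataset")
  .index_dataset(ds)
}

# Precompute per-layer integer structures used by the forward/backward pass.
.index_dataset <- function(ds) {
  N <- length(ds$universe)
  ds$node_idx <- lapply(ds$layers, function(g) match(g$nodes, ds$universe))
  ds$edge_idx <- lapply(ds$layers, function(g) {
    e <- matrix(match(g$edges, g$nodes), ncol = 2L)
    storage.mode(e) <- "integer"
    e
  })
  ds$Ahat <- Map(function(g, e) {
    normalized_adjacency(length(g$nodes), e)
  }, ds$layers, ds$edge_idx)
  # instance table: layer-major stacking of every (gene, layer) occurrence
  ds$inst_gene <- unlist(ds$node_idx, use.names = FALSE)
  ds$inst_layer <- rep.int(seq_along(ds$layers),
                           vapply(ds$node_idx, length, 0L))
  ds$n_inst <- length(ds$inst_gene)
  ds$k_meta <- tabulate(ds$inst_gene, N)
  ds$meta <- build_meta_graph(ds$layers, ds$universe)
  ds
}

#' @export
print.emgnn_dataset <- function(x, ...) {
  cat(sprintf("<emgnn_dataset: %d genes, %d layers (%s), %d features>\n",
              length(x$universe), length(x$layers),
              paste(x$layer_ids, collapse = ", "), ncol(x$X)))
  invisible(x)
}

#' Symmetric-normalized adjacency with implicit self-loops
#'
#' Returns the sparse matrix `D^{-1/2} (A + I) D^{-1/2}` with
#' `d_hat_i = 1 + deg(i)`, the propagation operator of GCN aggregation.
#'
#' @param n Number of nodes.
#' @param edge_idx Two-column integer matrix of undirected edges (1-based).
#' @return Sparse symmetric `n x n` Matrix.
#' @export
normalized_adjacency <- function(n, edge_idx) {
  if (n == 0L) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                           x = numeric(), dims = c(0L, 0L)))
  deg <- tabulate(c(edge_idx[, 1L], edge_idx[, 2L]), n)
  dh <- 1 / sqrt(1 + deg)
  i <- c(edge_idx[, 1L], edge_idx[, 2L], seq_len(n))
  j <- c(edge_idx[, 2L], edge_idx[, 1L], seq_len(n))
  Matrix::sparseMatrix(i = i, j = j, x = dh[i] * dh[j], dims = c(n, n))
}

#' Specify an input perturbation (ablation)
#'
#' @param mode One of `"none"`, `"random_features"` (replace the feature
#'   matrix by standard-normal noise), `"constant_features"` (all ones), or
#'   `"drop_edges"` (remove a fraction of edges per layer, uniformly without
#'   replacement).
#' @param fraction Edge-removal fraction in `[0,1]`; used only for
#'   `drop_edges`.
#' @param seed Integer seed.
#' @export
perturbation_spec <- function(mode = c("none", "random_features",
                                       "constant_features", "drop_edges"),
                              fraction = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "drop_edges" && (fraction < 0 || fraction > 1)) {
    .stopf("fraction must be in [0,1]")
  }
  structure(list(mode = mode, fraction = fraction, seed = as.integer(seed)),
            class = "emgnn_perturbation")
}

#' Apply an input perturbation to a dataset
#'
#' Returns a perturbed copy; the input dataset is not modified. Edge removal
#' draws `floor(fraction * |E_i|)` edges per layer, with a per-layer seed
#' `seed + layer index` so results do not depend on layer order.
#'
#' @param dataset An `emgnn_dataset`.
#' @param spec A [perturbation_spec()].
#' @return A perturbed `emgnn_dataset`.
#' @export
apply_perturbation <- function(dataset, spec) {
  stopifnot(inherits(dataset, "emgnn_dataset"),
            inherits(spec, "emgnn_perturbation"))
  ds <- dataset
  if (spec$mode == "none") return(ds)
  if (spec$mode == "random_features") {
    set.seed(spec$seed)
    ds$X[] <- rnorm(length(ds$X))
  } else if (spec$mode == "constant_features") {
    ds$X[] <- 1
  } else if (spec$mode == "drop_edges") {
    ds$layers <- lapply(seq_along(ds$layers), function(l) {
      g <- ds$layers[[l]]
      m <- nrow(g$edges)
      ndrop <- floor(spec$fraction * m)
      if (ndrop > 0L) {
        set.seed(spec$seed + l)
        drop <- sample.int(m, ndrop)
        g <- layer_graph(g$layer_id, g$edges[-drop, , drop = FALSE],
                         confidence = g$confidence[-drop], nodes = g$nodes)
      }
      g
    })
    ds <- .index_dataset(ds)
  }
  ds
}
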