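#' Construct an interaction-network layer
#'
#' A `LayerGraph` is one undirected gene-gene interaction network: a node set,
#' a set of unordered gene pairs, and optional per-edge confidence scores.
#' Self-loops are never stored (the GCN aggregation adds the self
#' contribution internally) and duplicate edges are collapsed, keeping the
#' maximum confidence seen for the pair.
#'
#' @param layer_id Short string naming the layer (e.g. `"STRING"`).
#' @param edges Two-column character matrix (or data.frame) of gene pairs.
#' @param confidence Optional numeric vector, one score in `[0,1]` per row of
#'   `edges`.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers to keep.
#' @return An object of class `emgnn_layer` with elements `layer_id`,
#'   `nodes`, `edges` (two-column character matrix, endpoints sorted
#'   byte-wise within each row) and `confidence`.
#' @examples
#' g <- layer_graph("L1", rbind(c("A", "B"), c("B", "A"), c("A", "A")))
#' nrow(g$edges) # 1
#' @export
layer_graph <- function(layer_id, edges, confidence = NULL, nodes = NULL) {
  stopifnot(is.character(layer_id), length(layer_id) == 1L)
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) .stopf("edges must have exactly 2 columns")
  mode(edges) <- "character"
  if (!is.null(confidence)) {
    stopifnot(length(confidence) == nrow(edges))
    confidence <- as.numeric(confidence)
  }
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  confidence <- confidence[keep]
  if (nrow(edges)) {
    swap <- order_pair_swap(edges)
    tmp <- edges[swap, 1L]
    edges[swap, 1L] <- edges[swap, 2L]
    edges[swap, 2L] <- tmp
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    if (anyDuplicated(key)) {
      if (!is.null(confidence)) {
        confidence <- vapply(split(confidence, key), max, numeric(1))
        edges <- do.call(rbind, strsplit(names(confidence), "\r", fixed = TRUE))
      } else {
        edges <- edges[!duplicated(key), , drop = FALSE]
      }
    }
    ord <- order(edges[, 1L], edges[, 2L], method = "radix")
    edges <- edges[ord, , drop = FALSE]
    if (!is.null(confidence)) confidence <- confidence[ord]
  }
  dimnames(edges) <- NULL
  confidence <- unname(confidence)
  nodes <- .csort(unique(c(as.vector(edges), nodes)))
  structure(
    list(layer_id = layer_id, nodes = nodes, edges = edges,
         confidence = confidence),
    class = "emgnn_layer"
  )
}

# TRUE for rows whose endpoints must be swapped to get byte-wise a < b
order_pair_swap <- function(edges) {
  xtfrm_a <- rank(edges[, 1L], ties.method = "min")
  # radix-consistent comparison: compare raw strings byte-wise
  mapply(function(a, b) identical(.csort(c(a, b))[1L], b) && a != b,
         edges[, 1L], edges[, 2L], USE.NAMES = FALSE)
}

#' @export
print.emgnn_layer <- function(x, ...) {
  cat(sprintf("<emgnn_layer '%s': %d nodes, %d edges%s>\n", x$layer_id,
              length(x$nodes), nrow(x$edges),
              if (is.null(x$confidence)) "" else ", scored"))
  invisible(x)
}

#' Read an interaction network from an edge-list file
#'
#' Parses a whitespace/tab-separated edge list with columns
#' `gene_a gene_b [confidence]`. Lines starting with `#` and blank lines are
#' ignored. When `min_confidence` is supplied, edges with confidence below the
#' threshold are removed and nodes left with degree zero after filtering are
#' dropped.
#'
#' @param path Path to the edge-list file.
#' @param layer_id Layer identifier to attach.
#' @param min_confidence Optional confidence threshold; edges with score
#'   `>= min_confidence` are kept. Requires a confidence column.
#' @return A [layer_graph()] object.
#' @export
load_layer_graph <- function(path, layer_id, min_confidence = NULL) {
  if (!file.exists(path)) .stopf("edge-list file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_idx)) .stopf("no edges in %s", path)
  toks <- strsplit(trimws(lines[data_idx]), "[ \t]+")
  nf <- lengths(toks)
  has_conf <- nf[1L] >= 3L
  bad <- which(nf < (if (has_conf) 3L else 2L))
  if (length(bad)) {
    .stopf("malformed edge list %s at line %d: expected %d columns",
           path, data_idx[bad[1L]], if (has_conf) 3L else 2L)
  }
  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, `[`, "", 2L)
  conf <- NULL
  if (has_conf) {
    conf <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
    if (anyNA(conf)) {
      .stopf("malformed edge list %s at line %d: non-numeric confidence",
             path, data_idx[which(is.na(conf))[1L]])
    }
  } else if (!is.null(min_confidence)) {
    .stopf("min_confidence given but %s has no confidence column", path)
  }
  if (!is.null(min_confidence)) {
    keep <- conf >= min_confidence
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
    # after confidence filtering, nodes left with degree 0 are dropped, so
    # only endpoints of surviving proper edges remain
    iso <- NULL
  } else {
    # a self-loop line encodes an isolated node: the loop itself is never
    # stored as an edge, but the node is kept (this is also how
    # write_layer_graph round-trips isolated nodes)
    iso <- a[a == b]
  }
  layer_graph(layer_id, cbind(a, b), confidence = conf, nodes = iso)
}

#' Write a layer to edge-list format
#'
#' Inverse of [load_layer_graph()]: writes `gene_a<TAB>gene_b[<TAB>conf]`
#' lines. Isolated nodes are written as self-loop lines (`g<TAB>g`), which
#' the loader converts back into isolated nodes, so a write/load round trip
#' preserves node and edge sets exactly.
#'
#' @param graph A [layer_graph()] object.
#' @param path Output file path.
#' @export
write_layer_graph <- function(graph, path) {
  stopifnot(inherits(graph, "emgnn_layer"))
  iso <- setdiff(graph$nodes, unique(as.vector(graph$edges)))
  a <- c(graph$edges[, 1L], iso)
  b <- c(graph$edges[, 2L], iso)
  df <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  if (!is.null(graph$confidence)) {
    df$confidence <- c(graph$confidence, rep(1, length(iso)))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Neighbors of a gene within one layer
#' @param graph A [layer_graph()] object.
#' @param gene Gene identifier.
#' @return Character vector of neighboring genes (possibly empty).
#' @export
layer_neighbors <- function(graph, gene) {
  e <- graph$edges
  .csort(unique(c(e[e[, 2L] == gene, 1L], e[e[, 1L] == gene, 2L])))
}

#' Read a gene feature table
#'
#' TSV/CSV with the gene identifier in the first column and one header row of
#' feature names. Missing values are imputed as 0, which coincides with the
#' integrated-gradients baseline so imputed entries receive zero attribution
#' by construction.
#'
#' @param path File path. Delimiter is inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @return List of class `emgnn_features` with `genes`, `feature_names`, and
#'   the numeric `values` matrix (genes in rows).
#' @export
load_feature_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) .stopf("feature table %s needs >= 2 columns", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) .stopf("duplicate gene rows in %s", path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  mode(vals) <- "numeric"
  vals[is.na(vals)] <- 0
  feature_table(genes, colnames(vals), vals)
}

#' Construct a gene feature table in memory
#' @param genes Character vector of gene identifiers.
#' @param feature_names Character vector of unique feature names.
#' @param values Numeric matrix, `length(genes)` x `length(feature_names)`.
#' @export
feature_table <- function(genes, feature_names, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(genes),
            ncol(values) == length(feature_names))
  if (anyDuplicated(feature_names)) .stopf("feature names must be unique")
  if (anyNA(values)) values[is.na(values)] <- 0
  dimnames(values) <- list(genes, feature_names)
  structure(list(genes = genes, feature_names = feature_names,
                 values = values),
            class = "emgnn_features")
}

#' Positive/negative gene labels
#'
#' Genes not listed in either set are implicitly unlabeled.
#'
#' @param positives,negatives Character vectors of gene identifiers; must be
#'   disjoint.
#' @export
label_set <- function(positives, negatives) {
  positives <- .csort(unique(as.character(positives)))
  negatives <- .csort(unique(as.character(negatives)))
  if (length(intersect(positives, negatives))) {
    .stopf("positives and negatives overlap: %s",
           paste(head(intersect(positives, negatives), 3L), collapse = ", "))
  }
  structure(list(positives = positives, negatives = negatives),
            class = "emgnn_labels")
}

#' Read a label file
#'
#' TSV with columns `gene` and `label` (1 = positive, 0 = negative).
#'
#' @param path File path.
#' @return A [label_set()].
#' @export
load_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) .stopf("label file %s needs columns gene, label", path)
  lab <- df[[2L]]
  if (!all(lab %in% c(0L, 1L))) .stopf("labels in %s must be 0 or 1", path)
  label_set(df[[1L]][lab == 1L], df[[1L]][lab == 0L])
}

#' Build the shared gene universe
#'
#' The universe is the union of all layer node sets intersected with the
#' genes for which feature rows exist, in deterministic byte-wise
#' lexicographic order. Genes present in some layer but lacking features are
#' excluded (the model needs a feature vector for every node instance).
#'
#' @param layers List of [layer_graph()] objects.
#' @param features An `emgnn_features` table.
#' @return Ordered character vector of gene identifiers.
#' @export
build_gene_universe <- function(layers, features) {
  stopifnot(length(layers) > 0L)
  all_nodes <- unique(unlist(lapply(layers, `[[`, "nodes")))
  uni <- .csort(intersect(all_nodes, features$genes))
  if (!length(uni)) .stopf("no gene occurs in both the layers and the feature table")
  uni
}

#' Build the meta-graph over a gene universe
#'
#' Every (gene, layer) occurrence becomes an instance node; every universe
#' gene gets one meta-node; each occurrence contributes one meta-edge linking
#' the instance to its gene's meta-node. Genes found in a layer but absent
#' from the universe are skipped with a warning.
#'
#' @param layers List of [layer_graph()] objects.
#' @param universe Gene universe from [build_gene_universe()].
#' @return Object of class `emgnn_metagraph` with `meta_nodes` (the
#'   universe), `instances` (data.frame of `gene`, `layer_id`), and
#'   `n_meta_edges`.
#' @export
build_meta_graph <- function(layers, universe) {
  inst <- do.call(rbind, lapply(layers, function(g) {
    skip <- setdiff(g$nodes, universe)
    if (length(skip)) {
      .warnf("layer '%s': skipping %d gene(s) outside the universe",
             g$layer_id, length(skip))
    }
    keep <- intersect(g$nodes, universe)
    if (!length(keep)) return(NULL)
    data.frame(gene = keep, layer_id = g$layer_id, stringsAsFactors = FALSE)
  }))
  if (is.null(inst)) inst <- data.frame(gene = character(), layer_id = character())
  structure(list(meta_nodes = universe, instances = inst,
                 n_meta_edges = nrow(inst)),
            class = "emgnn_metagraph")
}

#' Number of meta-edges per gene
#' @param meta An `emgnn_metagraph`.
#' @return Named integer vector over the universe.
#' @export
meta_edge_counts <- function(meta) {
  k <- table(factor(meta$instances$gene, levels = meta$meta_nodes))
  setNames(as.integer(k), meta$meta_nodes)
}
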