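#' Specify a synthetic multilayer benchmark
#'
#' Describes a seeded synthetic world mimicking the shape of real multilayer
#' gene-classification data: `n_layers` interaction networks over a shared
#' gene universe, genes randomly absent from some layers, a real-valued
#' feature matrix in which a subset of columns is shifted for positive
#' genes, and planted homophilous topology in the informative layers
#' (positive-positive pairs are wired with elevated probability
#' `edge_density + 0.2 * homophily`; all other pairs, and all pairs in
#' non-informative layers, follow an Erdos-Renyi model at `edge_density`).
#'
#' Default scale (600 genes, 3 layers, 64 features, ~10% positive among
#' labeled genes) is a desk-scale analogue of the real pan-cancer setting
#' (tens of thousands of genes, 6 networks, 16 cancer types x 4 omics
#' features, 887 positive / 7753 negative labeled genes).
#'
#' @param n_genes Number of genes in the universe.
#' @param n_layers Number of network layers.
#' @param d_features Feature dimension.
#' @param informative_features Number of leading feature columns shifted by
#'   `effect_size` for positive genes.
#' @param informative_layers Integer indices of layers with planted
#'   homophily.
#' @param homophily Strength in `[0,1]` of the planted topological signal.
#' @param edge_density Baseline edge probability.
#' @param missing_gene_rate Probability that a gene is absent from a given
#'   layer (genes absent everywhere are reassigned to one random layer).
#' @param label_prevalence Probability that a gene's true class is positive.
#' @param labeled_fraction Fraction of genes with observed labels; the rest
#'   are unlabeled (their true class is kept in the ground-truth record).
#' @param noise_sd Standard deviation of the feature noise.
#' @param effect_size Mean shift of informative features for positives.
#' @param seed Integer seed; the bundle is fully reproducible from it.
#' @export
benchmark_spec <- function(n_genes = 600L, n_layers = 3L, d_features = 64L,
                           informative_features = 8L,
                           informative_layers = 1L, homophily = 0.8,
                           edge_density = 0.01, missing_gene_rate = 0.1,
                           label_prevalence = 0.103,
                           labeled_fraction = 0.7, noise_sd = 1,
                           effect_size = 1, seed = 1L) {
  stopifnot(n_genes >= 10L, n_layers >= 1L, d_features >= 1L,
            informative_features <= d_features, informative_features >= 0L,
            homophily >= 0, homophily <= 1,
            edge_density > 0, edge_density <= 1,
            missing_gene_rate >= 0, missing_gene_rate < 1,
            label_prevalence > 0, label_prevalence < 1,
            labeled_fraction > 0, labeled_fraction <= 1,
            noise_sd > 0)
  informative_layers <- as.integer(informative_layers)
  if (length(informative_layers) &&
      (any(informative_layers < 1L) || any(informative_layers > n_layers))) {
    .stopf("informative_layers must be within 1..n_layers")
  }
  structure(list(n_genes = as.integer(n_genes), n_layers = as.integer(n_layers),
                 d_features = as.integer(d_features),
                 informative_features = as.integer(informative_features),
                 informative_layers = informative_layers,
                 homophily = homophily, edge_density = edge_density,
                 missing_gene_rate = missing_gene_rate,
                 label_prevalence = label_prevalence,
                 labeled_fraction = labeled_fraction,
                 noise_sd = noise_sd, effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "emgnn_benchmark_spec")
}

#' Generate a synthetic multilayer benchmark
#'
#' @param spec A [benchmark_spec()].
#' @return List of class `emgnn_benchmark` with `layers` (list of
#'   [layer_graph()]), `features` (an `emgnn_features`), `labels` (a
#'   [label_set()] over the labeled subset), and `truth`: the ground-truth
#'   record (the spec, every gene's true class, the labeled/unlabeled
#'   partition and per-layer membership).
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "emgnn_benchmark_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  cls <- rbinom(n, 1L, spec$label_prevalence)
  if (sum(cls) == 0L || sum(cls) == n) {
    .stopf("spec produced an empty class; increase n_genes or adjust prevalence")
  }
  # features: noise + mean shift on informative columns for positives
  X <- matrix(rnorm(n * spec$d_features, sd = spec$noise_sd),
              n, spec$d_features)
  if (spec$informative_features > 0L) {
    ic <- seq_len(spec$informative_features)
    X[cls == 1L, ic] <- X[cls == 1L, ic] + spec$effect_size
  }
  colnames(X) <- sprintf("f%03d", seq_len(spec$d_features))
  features <- feature_table(genes, colnames(X), X)

  # per-layer membership; resample genes absent from every layer
  member <- matrix(runif(n * spec$n_layers) >= spec$missing_gene_rate,
                   n, spec$n_layers)
  orphan <- which(rowSums(member) == 0L)
  if (length(orphan)) {
    member[cbind(orphan, sample.int(spec$n_layers, length(orphan),
                                    replace = TRUE))] <- TRUE
  }

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p_hom <- min(1, spec$edge_density + 0.2 * spec$homophily)
  layers <- lapply(seq_len(spec$n_layers), function(l) {
    inl <- member[, l]
    ok <- inl[pairs[, 1L]] & inl[pairs[, 2L]]
    pp <- cls[pairs[, 1L]] == 1L & cls[pairs[, 2L]] == 1L
    prob <- ifelse(pp & l %in% spec$informative_layers, p_hom,
                   spec$edge_density)
    keep <- ok & (runif(nrow(pairs)) < prob)
    e <- cbind(genes[pairs[keep, 1L]], genes[pairs[keep, 2L]])
    layer_graph(sprintf("L%d", l), e, nodes = genes[inl])
  })

  labeled <- sort(sample.int(n, round(spec$labeled_fraction * n)))
  pos <- genes[intersect(labeled, which(cls == 1L))]
  neg <- genes[intersect(labeled, which(cls == 0L))]
  if (!length(pos) || !length(neg)) {
    .stopf("spec produced an empty labeled class")
  }
  truth <- list(spec = unclass(spec), genes = genes, true_class = cls,
                labeled = genes[labeled],
                membership = member,
                p_within_positive = p_hom)
  structure(list(layers = layers, features = features,
                 labels = label_set(pos, neg), truth = truth),
            class = "emgnn_benchmark")
}

#' @export
print.emgnn_benchmark <- function(x, ...) {
  cat(sprintf(
    "<emgnn_benchmark: %d genes, %d layers, %d features, %d+/%d- labeled>\n",
    length(x$features$genes), length(x$layers), ncol(x$features$values),
    length(x$labels$positives), length(x$labels$negatives)))
  invisible(x)
}

#' Write a benchmark bundle to disk
#'
#' Emits one edge-list TSV per layer (`layer_<id>.tsv`), `features.tsv`,
#' `labels.tsv` and `truth.json`, all loadable by the package's readers.
#' Writing the same bundle twice produces byte-identical files.
#'
#' @param bundle An `emgnn_benchmark`.
#' @param directory Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_benchmark <- function(bundle, directory) {
  stopifnot(inherits(bundle, "emgnn_benchmark"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    .stopf("cannot create directory %s", directory)
  }
  for (g in bundle$layers) {
    write_layer_graph(g, file.path(directory,
                                   sprintf("layer_%s.tsv", g$layer_id)))
  }
  ft <- bundle$features
  df <- data.frame(gene = ft$genes, ft$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file.path(directory, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lab <- rbind(
    data.frame(gene = bundle$labels$positives, label = 1L),
    data.frame(gene = bundle$labels$negatives, label = 0L))
  lab <- lab[order(lab$gene, method = "radix"), ]
  write.table(lab, file.path(directory, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(directory, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(directory)
}

#' Load a benchmark directory written by [write_benchmark()]
#' @param directory Directory path.
#' @return An `emgnn_benchmark` (with `truth` if `truth.json` is present).
#' @export
load_benchmark <- function(directory) {
  lf <- .csort(list.files(directory, pattern = "^layer_.*\\.tsv$",
                          full.names = TRUE))
  if (!length(lf)) .stopf("no layer_*.tsv files in %s", directory)
  layers <- lapply(lf, function(f) {
    id <- sub("^layer_(.*)\\.tsv$", "\\1", basename(f))
    load_layer_graph(f, id)
  })
  features <- load_feature_table(file.path(directory, "features.tsv"))
  labels <- load_labels(file.path(directory, "labels.tsv"))
  truth <- NULL
  tf <- file.path(directory, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(layers = layers, features = features, labels = labels,
                 truth = truth), class = "emgnn_benchmark")
}
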