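#' Fraction of positively labeled neighbors
#'
#' For a gene with degree >= 1 in a layer, the number of neighbors labeled
#' positive divided by the gene's degree in that layer.
#'
#' @param gene Gene identifier.
#' @param layer A [layer_graph()].
#' @param labels A [label_set()].
#' @return Value in `[0,1]`.
#' @export
cancer_neighbor_fraction <- function(gene, layer, labels) {
  nb <- layer_neighbors(layer, gene)
  if (!length(nb)) {
    .stopf("gene '%s' has degree 0 in layer '%s'; fraction undefined",
           gene, layer$layer_id)
  }
  sum(nb %in% labels$positives) / length(nb)
}

#' Meta-edge variance / cancer-neighborhood correlation analysis
#'
#' For each gene with at least `min_layers` layers where both its normalized
#' meta-edge importance and its cancer-neighbor fraction are defined,
#' computes the standard deviation of meta-edge importance across layers and
#' the Pearson correlation between importance and neighbor fraction. Genes
#' with a constant vector on either side are skipped (correlation
#' undefined). Genes are then stratified into high/low variance groups at
#' the median standard deviation and the mean correlation per group is
#' reported; a higher mean correlation in the high-variance group indicates
#' that network importance tracks the cancer neighborhood exactly where
#' importance varies across networks.
#'
#' @param attributions Numeric matrix genes x layers of normalized meta-edge
#'   importances (`NA` where a gene is absent from a layer).
#' @param fractions Numeric matrix of identical shape with cancer-neighbor
#'   fractions (`NA` where undefined).
#' @param min_layers Minimum number of jointly defined layers per gene.
#' @return List with `per_gene` (data.frame `gene`, `sd_importance`,
#'   `pearson_r`, `n_layers`) and `group_summary` (data.frame `group`,
#'   `n`, `mean_r`).
#' @export
meta_edge_correlation_analysis <- function(attributions, fractions,
                                           min_layers = 3L) {
  stopifnot(all(dim(attributions) == dim(fractions)))
  genes <- rownames(attributions)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(attributions)))
  rows <- lapply(seq_len(nrow(attributions)), function(i) {
    a <- attributions[i, ]; f <- fractions[i, ]
    ok <- !is.na(a) & !is.na(f)
    if (sum(ok) < min_layers) return(NULL)
    a <- a[ok]; f <- f[ok]
    if (sd(a) == 0 || sd(f) == 0) {
      .warnf("gene '%s': constant vector, correlation undefined; skipped",
             genes[i])
      return(NULL)
    }
    data.frame(gene = genes[i], sd_importance = sd(a),
               pearson_r = cor(a, f), n_layers = sum(ok),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene) || !nrow(per_gene)) {
    .stopf("no gene has >= %d layers with defined values", min_layers)
  }
  med <- stats::median(per_gene$sd_importance)
  grp <- ifelse(per_gene$sd_importance > med, "high_sd", "low_sd")
  gs <- do.call(rbind, lapply(c("high_sd", "low_sd"), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel),
               mean_r = if (any(sel)) mean(per_gene$pearson_r[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_gene = per_gene, group_summary = gs)
}

#' One-way ANOVA of meta-edge importance across layers
#'
#' Treats layers as groups and per-gene normalized meta-edge attributions as
#' observations; tests whether some networks contribute systematically more
#' than others.
#'
#' @param attributions Numeric matrix genes x layers (`NA` allowed), or a
#'   list of numeric vectors (one per layer).
#' @return List with `F` statistic, `p_value`, and degrees of freedom
#'   `df1`, `df2`.
#' @export
anova_across_layers <- function(attributions) {
  if (is.matrix(attributions) || is.data.frame(attributions)) {
    groups <- lapply(seq_len(ncol(attributions)), function(j) {
      v <- attributions[, j]
      v[!is.na(v)]
    })
    names(groups) <- colnames(attributions)
  } else {
    groups <- lapply(attributions, function(v) v[!is.na(v)])
  }
  k <- length(groups)
  if (k < 2L) .stopf("ANOVA needs >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) .stopf("every group needs >= 2 observations")
  n <- sum(ns)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 0)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (ssb == 0) return(list(F = 0, p_value = 1, df1 = k - 1L, df2 = n - k))
  if (ssw == 0) .stopf("zero within-group variance; F undefined")
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p_value = pf(f, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1L, df2 = n - k)
}

#' Read gene sets in GMT format
#'
#' One tab-separated line per set: `set_name<TAB>description<TAB>gene...`.
#'
#' @param path GMT file path.
#' @return Object of class `emgnn_genesets`: list with `sets` (named list of
#'   character vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(toks) < 3L)
  if (length(bad)) .stopf("malformed GMT %s at line %d", path, bad[1L])
  nms <- vapply(toks, `[`, "", 1L)
  if (anyDuplicated(nms)) .stopf("duplicate set names in %s", path)
  sets <- lapply(toks, function(t) unique(t[-(1:2)]))
  names(sets) <- nms
  gene_set_collection(sets,
                      description = setNames(vapply(toks, `[`, "", 2L), nms))
}

#' Construct a gene-set collection
#' @param sets Named list of non-empty character vectors.
#' @param description Optional named character vector of set descriptions.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) .stopf("set names must be unique")
  if (any(lengths(sets) == 0L)) .stopf("every gene set must be non-empty")
  structure(list(sets = sets, description = description),
            class = "emgnn_genesets")
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score of `hits`
# (logical over the ranked list) with rank weights `r` (importances).
.gsea_es <- function(hits, r, weight_p = 1) {
  n <- length(hits)
  nh <- sum(hits)
  w <- abs(r)^weight_p
  wh <- w * hits
  denom <- sum(wh)
  inc <- if (denom > 0) wh / denom else hits / nh
  dec <- (!hits) / (n - nh)
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov preranked GSEA: walking down the
#' ranked list, the running sum increases proportionally to
#' `|importance|^weight_p` at set members and decreases by `1/(N - N_h)`
#' elsewhere; the enrichment score (ES) is the maximum deviation from zero.
#' Significance is assessed by permuting which genes are set members on the
#' fixed ranking (`n_perm` permutations, seeded per set as `seed + set
#' index`); p-values are one-sided in the direction of the observed ES and
#' include the observed statistic (`(1 + exceed) / (1 + n_perm)`).
#' Benjamini-Hochberg FDR is computed across all evaluated sets. Sets whose
#' overlap with the ranked list is below `min_size`, above `max_size`, or
#' equal to the whole list are skipped with a warning.
#'
#' @param ranked data.frame with columns `gene`, `importance`, ordered by
#'   decreasing importance (the order given is used as the ranking).
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param weight_p Rank-weight exponent (0 = classic KS, 1 = weighted).
#' @param min_size,max_size Overlap-size filters.
#' @return data.frame of class `emgnn_enrichment`: `set_name`, `size`, `es`,
#'   `p_value`, `fdr`, `leading_edge` (comma-separated genes).
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           weight_p = 1, min_size = 5L, max_size = 500L) {
  stopifnot(is.data.frame(ranked), all(c("gene", "importance") %in% names(ranked)))
  if (anyDuplicated(ranked$gene)) .stopf("ranked list has duplicate genes")
  genes <- ranked$gene
  r <- ranked$importance
  n <- length(genes)
  out <- list()
  for (si in seq_along(sets$sets)) {
    nm <- names(sets$sets)[si]
    members <- intersect(sets$sets[[si]], genes)
    sz <- length(members)
    if (sz < min_size || sz > max_size || sz == n) {
      .warnf("set '%s' skipped (overlap %d)", nm, sz)
      next
    }
    hits <- genes %in% members
    es <- .gsea_es(hits, r, weight_p)
    set.seed(seed + si)
    perm <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, sz)] <- TRUE
      .gsea_es(h, r, weight_p)
    }, 0)
    exceed <- if (es >= 0) sum(perm >= es) else sum(perm <= es)
    pval <- (1 + exceed) / (1 + n_perm)
    # leading edge: members at or before the running-sum peak (positive ES)
    # or at/after it (negative ES)
    w <- abs(r)^weight_p
    wh <- w * hits
    denom <- sum(wh)
    inc <- if (denom > 0) wh / denom else hits / sz
    run <- cumsum(inc - (!hits) / (n - sz))
    peak <- which.max(abs(run))
    le <- if (es >= 0) genes[seq_len(peak)][hits[seq_len(peak)]] else
      genes[peak:n][hits[peak:n]]
    out[[nm]] <- data.frame(set_name = nm, size = sz, es = es,
                            p_value = pval,
                            leading_edge = paste(le, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) .stopf("no gene set passed the size filters")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res <- res[, c("set_name", "size", "es", "p_value", "fdr", "leading_edge")]
  class(res) <- c("emgnn_enrichment", "data.frame")
  res
}
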