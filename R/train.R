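#' Build train/validation/test splits
#'
#' Follows the multilayer evaluation protocol: the labeled genes of the
#' designated test layer are split 75%/25% by stratified sampling (equal
#' class proportions up to rounding); the 25% part is the held-out test set.
#' All remaining labeled genes -- from any supplied layer, excluding test
#' genes -- are split 90%/10% into training and validation, again per class.
#' The test set depends only on `(test_layer, seed)`: it is bit-identical no
#' matter which or how many additional layers are supplied.
#'
#' @param labels A [label_set()].
#' @param layers List of [layer_graph()] objects.
#' @param test_layer `layer_id` of the layer whose labeled genes are held
#'   out.
#' @param seed Integer seed.
#' @return Object of class `emgnn_split` with `test_layer`, `train_genes`,
#'   `val_genes`, `test_genes`, `seed`.
#' @export
make_splits <- function(labels, layers, test_layer, seed = 1L) {
  ids <- vapply(layers, `[[`, "", "layer_id")
  if (!test_layer %in% ids) .stopf("test_layer '%s' not among layers", test_layer)
  tl <- layers[[match(test_layer, ids)]]
  pos_t <- .csort(intersect(tl$nodes, labels$positives))
  neg_t <- .csort(intersect(tl$nodes, labels$negatives))
  if (length(pos_t) < 4L || length(neg_t) < 4L) {
    .stopf("test layer '%s' needs >= 4 labeled genes per class (has %d/%d)",
           test_layer, length(pos_t), length(neg_t))
  }
  take_test <- function(genes) {
    n <- round(0.25 * length(genes))
    .csort(genes[sample.int(length(genes), n)])
  }
  set.seed(seed)
  test_genes <- c(take_test(pos_t), take_test(neg_t))

  all_nodes <- unique(unlist(lapply(layers, `[[`, "nodes")))
  pos_r <- setdiff(.csort(intersect(all_nodes, labels$positives)), test_genes)
  neg_r <- setdiff(.csort(intersect(all_nodes, labels$negatives)), test_genes)
  take_val <- function(genes) {
    n <- round(0.10 * length(genes))
    genes[sample.int(length(genes), n)]
  }
  set.seed(seed + 1L)
  val_genes <- c(take_val(pos_r), take_val(neg_r))
  train_genes <- setdiff(c(pos_r, neg_r), val_genes)
  structure(list(test_layer = test_layer,
                 train_genes = .csort(train_genes),
                 val_genes = .csort(val_genes),
                 test_genes = .csort(test_genes),
                 seed = as.integer(seed)),
            class = "emgnn_split")
}

#' Area under the precision-recall curve
#'
#' Average precision with tied scores grouped: documents with equal scores
#' are treated as retrieved together, so a constant score vector yields the
#' label prevalence. No interpolation is applied.
#'
#' @param scores Numeric vector.
#' @param labels Binary (0/1) vector of the same length.
#' @return AUPRC in `[0,1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (all(labels == 1L) || all(labels == 0L)) {
    .stopf("auprc needs both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  pos_in_grp <- tapply(y, grp, sum)
  n_in_grp <- tapply(y, grp, length)
  cum_tp <- cumsum(pos_in_grp)
  cum_n <- cumsum(n_in_grp)
  sum(pos_in_grp * (cum_tp / cum_n)) / sum(y)
}

.adam_init <- function(p) {
  list(m = .zero_like(p), v = .zero_like(p), t = 0L)
}

.rmap2 <- function(a, b, f) {
  if (is.list(a)) return(Map(function(x, y) .rmap2(x, y, f), a, b))
  f(a, b)
}
.rmap3 <- function(a, b, c, f) {
  if (is.list(a)) return(Map(function(x, y, z) .rmap3(x, y, z, f), a, b, c))
  f(a, b, c)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .rmap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .rmap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .rmap3(params, state$m, state$v, function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  list(params = params, state = state)
}

# Cross-entropy from logits (numerically stable).
.ce_from_logits <- function(logits, y) {
  mx <- pmax(logits[, 1L], logits[, 2L])
  lse <- mx + log(exp(logits[, 1L] - mx) + exp(logits[, 2L] - mx))
  mean(lse - ifelse(y == 1L, logits[, 2L], logits[, 1L]))
}

#' Train a multilayer GNN
#'
#' Full-batch training that minimizes the cross-entropy of the meta-node
#' outputs over the training genes with the Adam optimizer. The validation
#' AUPRC is evaluated every `eval_every` epochs (dropout off) and the
#' parameters with the best validation AUPRC are returned, alongside the
#' final-epoch parameters. All randomness (dropout) is seeded from the model
#' configuration seed, so runs are reproducible.
#'
#' @param model An (untrained) [emgnn_model()].
#' @param dataset An `emgnn_dataset` with labels.
#' @param split An `emgnn_split` from [make_splits()].
#' @param epochs Number of epochs (reference protocol: 2000).
#' @param lr Adam learning rate (reference protocol: 0.001).
#' @param weight_decay L2 penalty added to weight-matrix gradients
#'   (biases excluded).
#' @param eval_every Validation evaluation interval in epochs.
#' @param verbose Print progress every evaluation.
#' @return List with `model` (best-validation checkpoint), `last_model`, and
#'   `report` (class `emgnn_train_report`): per-epoch training loss,
#'   validation AUPRC trace, `best_epoch`, `test_auprc`, config echo, seed.
#' @export
train_emgnn <- function(model, dataset, split, epochs = 2000L, lr = 1e-3,
                        weight_decay = 5e-4, eval_every = 10L,
                        verbose = FALSE) {
  stopifnot(inherits(model, "emgnn_model"), inherits(dataset, "emgnn_dataset"),
            inherits(split, "emgnn_split"))
  if (is.null(dataset$labels)) .stopf("dataset has no labels")
  uni <- dataset$universe
  idx_of <- function(genes) {
    i <- match(genes, uni)
    i[!is.na(i)]
  }
  y_of <- function(idx) as.integer(uni[idx] %in% dataset$labels$positives)
  tr_idx <- idx_of(split$train_genes); tr_y <- y_of(tr_idx)
  va_idx <- idx_of(split$val_genes);  va_y <- y_of(va_idx)
  te_idx <- idx_of(split$test_genes); te_y <- y_of(te_idx)
  if (!length(tr_idx)) .stopf("no training genes present in the dataset")

  if (model$config$conv_type == "gat") {
    dataset <- .prepare_structs(dataset, model)
  }
  n_tr <- length(tr_idx)
  state <- .adam_init(model$params)
  loss_hist <- numeric(epochs)
  val_epochs <- integer(0); val_auprc <- numeric(0)
  best <- list(auprc = -Inf, params = model$params, epoch = 0L)
  set.seed(model$config$seed + 10000L)  # dropout stream
  for (ep in seq_len(epochs)) {
    fw <- .emgnn_forward(model, dataset, training = TRUE)
    loss <- .ce_from_logits(fw$logits[tr_idx, , drop = FALSE], tr_y)
    if (!is.finite(loss)) {
      .stopf("non-finite training loss at epoch %d (lr=%g); aborting", ep, lr)
    }
    loss_hist[ep] <- loss
    dlogits <- matrix(0, length(uni), 2L)
    P <- fw$prob[tr_idx, , drop = FALSE]
    onehot <- cbind(1L - tr_y, tr_y)
    dlogits[tr_idx, ] <- (P - onehot) / n_tr
    bw <- .emgnn_backward(model, fw, dlogits, need_params = TRUE)
    g <- bw$params
    if (weight_decay > 0) {
      g <- .add_weight_decay(g, model$params, weight_decay)
    }
    upd <- .adam_step(model$params, g, state, lr)
    model$params <- upd$params
    state <- upd$state
    if (ep %% eval_every == 0L || ep == epochs) {
      if (length(va_idx) && length(unique(va_y)) == 2L) {
        ev <- .emgnn_forward(model, dataset)
        va <- auprc(ev$yhat[va_idx], va_y)
      } else {
        va <- NA_real_
      }
      val_epochs <- c(val_epochs, ep)
      val_auprc <- c(val_auprc, va)
      if (!is.na(va) && va > best$auprc) {
        best <- list(auprc = va, params = model$params, epoch = ep)
      }
      if (verbose) {
        message(sprintf("epoch %4d  loss %.4f  val AUPRC %s", ep, loss,
                        ifelse(is.na(va), "NA", sprintf("%.3f", va))))
      }
    }
  }
  if (!is.finite(best$auprc)) best <- list(auprc = NA_real_,
                                           params = model$params,
                                           epoch = epochs)
  best_model <- model
  best_model$params <- best$params
  best_model$trained <- TRUE
  model$trained <- TRUE
  test_auprc <- if (length(te_idx) && length(unique(te_y)) == 2L) {
    auprc(.emgnn_forward(best_model, dataset)$yhat[te_idx], te_y)
  } else NA_real_
  report <- structure(list(
    loss = loss_hist, val_epochs = val_epochs, val_auprc = val_auprc,
    best_epoch = best$epoch, best_val_auprc = best$auprc,
    test_auprc = test_auprc, epochs = epochs, lr = lr,
    weight_decay = weight_decay, config = model$config,
    seed = model$config$seed), class = "emgnn_train_report")
  list(model = best_model, last_model = model, report = report)
}

.add_weight_decay <- function(g, p, wd) {
  walk <- function(gg, pp, nm) {
    if (is.list(gg)) {
      nms <- if (is.null(names(gg))) vector("list", length(gg)) else
        as.list(names(gg))
      return(Map(walk, gg, pp, nms))
    }
    if (is.matrix(gg) && !is.null(nm) && grepl("^W", nm)) gg + wd * pp else gg
  }
  walk(g, p, NULL)
}

#' @export
print.emgnn_train_report <- function(x, ...) {
  cat(sprintf(
    "<emgnn_train_report: %d epochs, best epoch %d (val AUPRC %.3f), test AUPRC %s>\n",
    x$epochs, x$best_epoch, x$best_val_auprc,
    ifelse(is.na(x$test_auprc), "NA", sprintf("%.3f", x$test_auprc))))
  invisible(x)
}

#' Majority-vote ensemble of binary predictions
#'
#' Per-gene majority over equal-length binary prediction vectors; an even
#' split is resolved to the positive class (recall-favoring convention for
#' screening applications).
#'
#' @param per_layer_predictions List of equal-length binary (0/1) vectors,
#'   or a matrix with one column per predictor.
#' @return Binary integer vector.
#' @export
majority_vote <- function(per_layer_predictions) {
  if (is.list(per_layer_predictions)) {
    lens <- lengths(per_layer_predictions)
    if (length(unique(lens)) != 1L) .stopf("prediction vectors differ in length")
    M <- do.call(cbind, per_layer_predictions)
  } else {
    M <- as.matrix(per_layer_predictions)
  }
  if (ncol(M) < 1L) .stopf("need at least one predictor")
  as.integer(rowMeans(M) >= 0.5)
}

#' Precision-thresholded selection of unlabeled genes
#'
#' Finds the smallest score threshold at which the precision over the
#' labeled genes reaches `target_precision`, then returns the unlabeled
#' genes scoring at or above it, ranked by predicted probability.
#'
#' @param scores Named numeric vector of scores for *labeled* genes.
#' @param labels Binary vector aligned with `scores`.
#' @param unlabeled_scores Named numeric vector of scores for unlabeled
#'   genes.
#' @param target_precision Required precision in `(0, 1]`.
#' @return List with `threshold`, `precision` (achieved on labeled genes at
#'   the threshold) and `selected`: a data.frame `gene`, `yhat`, `rank` in
#'   descending score order.
#' @export
precision_threshold_cutoff <- function(scores, labels, unlabeled_scores,
                                       target_precision = 0.95) {
  stopifnot(length(scores) == length(labels),
            target_precision > 0, target_precision <= 1)
  labels <- as.integer(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  prec <- vapply(thr, function(t) {
    sel <- scores >= t
    sum(labels[sel]) / sum(sel)
  }, 0)
  ok <- which(prec >= target_precision)
  if (!length(ok)) {
    .stopf("target precision %.3f unattainable; maximum achievable is %.3f",
           target_precision, max(prec))
  }
  t_star <- min(thr[ok])
  p_star <- prec[max(ok)]
  sel <- unlabeled_scores[unlabeled_scores >= t_star]
  sel <- sort(sel, decreasing = TRUE)
  list(threshold = t_star, precision = p_star,
       selected = data.frame(gene = names(sel), yhat = as.numeric(sel),
                             rank = seq_along(sel),
                             stringsAsFactors = FALSE))
}

#' Save a model checkpoint
#'
#' Writes a single JSON file holding a versioned header, the configuration,
#' the input dimension, an optional gene universe, and all parameters.
#'
#' @param model An `emgnn_model`.
#' @param path Output path.
#' @param universe Optional gene universe to embed.
#' @export
save_emgnn <- function(model, path, universe = NULL) {
  obj <- list(format = "emgnn-checkpoint", version = 1L,
              config = unclass(model$config), d_in = model$d_in,
              trained = isTRUE(model$trained), universe = universe,
              params = model$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_emgnn()]
#' @param path Checkpoint path.
#' @return List with `model` and `universe` (possibly `NULL`).
#' @export
load_emgnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "emgnn-checkpoint")) {
    .stopf("%s is not an emgnn checkpoint", path)
  }
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- emgnn_model(cfg, obj$d_in)
  model$params <- .restore_params(model$params, obj$params)
  model$trained <- isTRUE(obj$trained)
  list(model = model, universe = obj$universe)
}

# jsonlite round-trips matrices faithfully but biases arrive as vectors;
# coerce every leaf back to the template's shape.
.restore_params <- function(template, loaded) {
  if (is.list(template)) {
    sel <- if (is.null(names(template))) loaded else loaded[names(template)]
    return(Map(.restore_params, template, sel))
  }
  if (is.matrix(template)) {
    matrix(as.numeric(loaded), nrow(template), ncol(template))
  } else {
    as.numeric(loaded)
  }
}
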