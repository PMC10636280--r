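test_that("gcn_aggregate matches the closed form on simple graphs", {
  # two connected nodes: d_hat = 2 for both, so h'_u = (h_u + h_v) / 2
  H <- rbind(c(1, 0), c(0, 1))
  out <- gcn_aggregate(H, rbind(c(1L, 2L)), diag(2))
  expect_equal(out[1, ], c(0.5, 0.5))
  expect_equal(out[2, ], c(0.5, 0.5))
  # isolated node: self-loop only, d_hat = 1
  out2 <- gcn_aggregate(H, matrix(integer(), ncol = 2), diag(2))
  expect_equal(out2, H)
  expect_error(gcn_aggregate(H, rbind(c(1L, 2L)), diag(3)),
               "dimension mismatch")
})

test_that("gcn_aggregate equals the dense normalized-adjacency oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    e <- rand_connected_graph(n)
    H <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    expect_equal(gcn_aggregate(H, e, W), dense_gcn_oracle(H, e, W),
                 tolerance = 1e-10)
  }
})

test_that("gat_aggregate: zero attention vector averages the closed neighborhood", {
  set.seed(4)
  H <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(9), 3, 3)
  e <- rbind(c(1L, 2L), c(2L, 3L))
  out <- gat_aggregate(H, e, W, rep(0, 6))
  G <- H %*% W
  expect_equal(out[1, ], colMeans(G[c(1, 2), ]))       # N(1) = {2}
  expect_equal(out[2, ], colMeans(G[1:3, ]))           # N(2) = {1,3}
  expect_equal(out[4, ], G[4, ])                       # isolated: alpha_uu = 1
})

test_that("gat_aggregate matches a brute-force softmax oracle", {
  set.seed(31)
  n <- 6
  e <- rand_connected_graph(n)
  H <- matrix(rnorm(n * 3), n, 3)
  W <- matrix(rnorm(3 * 4), 3, 4)
  a <- rnorm(8)
  res <- gat_aggregate(H, e, W, a, leaky_slope = 0.2, return_attention = TRUE)
  oracle <- gat_oracle(H, e, W, a, slope = 0.2)
  expect_equal(res$states, oracle$out, tolerance = 1e-10)
  # attention rows sum to 1 over each closed neighborhood
  sums <- tapply(res$attention$alpha, res$attention$dst, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # coefficient-level agreement with the per-node oracle
  for (u in seq_len(n)) {
    mine <- res$attention[res$attention$dst == u, ]
    expect_equal(setNames(mine$alpha, mine$src),
                 oracle$alpha[[u]][as.character(mine$src)],
                 tolerance = 1e-10)
  }
})

test_that("forward returns probabilities and is deterministic given the seed", {
  ds <- toy_dataset()
  for (conv in c("gcn", "gat")) {
    cfg <- model_config(conv, f1_hidden = 8, f2_hidden = 8, gat_heads = 2,
                        seed = 5)
    m <- emgnn_model(cfg, ncol(ds$X))
    y1 <- emgnn_forward(m, ds)
    y2 <- emgnn_forward(m, ds)
    expect_identical(y1, y2)
    expect_true(all(y1 >= 0 & y1 <= 1))
    expect_named(y1, ds$universe)
  }
})

test_that("duplicated layers give identical instance states under shared f1", {
  ds <- toy_dataset()
  g <- ds$layers[[1]]
  dup <- layer_graph("Acopy", g$edges, nodes = g$nodes)
  ft <- feature_table(rownames(ds$X), colnames(ds$X), ds$X)
  ds2 <- multilayer_dataset(list(g, dup), ft)
  m <- emgnn_model(model_config(f1_hidden = 8, f2_hidden = 8, seed = 1),
                   ncol(ds2$X))
  fw <- emgnn:::.emgnn_forward(m, ds2)
  n1 <- length(ds2$node_idx[[1]])
  expect_equal(fw$Hinst[seq_len(n1), ], fw$Hinst[n1 + seq_len(n1), ])
})

test_that("forward is invariant to layer order and to gene permutation", {
  ds <- toy_dataset()
  m <- emgnn_model(model_config(f1_hidden = 8, f2_hidden = 8, seed = 2),
                   ncol(ds$X))
  y <- emgnn_forward(m, ds)
  ft <- feature_table(rownames(ds$X), colnames(ds$X), ds$X)
  ds_rev <- multilayer_dataset(rev(ds$layers), ft, ds$labels)
  expect_equal(emgnn_forward(m, ds_rev), y, tolerance = 1e-12)

  # permuting the gene order of all inputs permutes yhat identically
  set.seed(8)
  perm <- sample(nrow(ds$X))
  ft_p <- feature_table(rownames(ds$X)[perm], colnames(ds$X),
                        ds$X[perm, , drop = FALSE])
  ds_p <- multilayer_dataset(ds$layers, ft_p, ds$labels)
  y_p <- emgnn_forward(m, ds_p)
  expect_equal(y_p[names(y)], y, tolerance = 1e-12)
})

test_that("a gene's prediction ignores layers that do not contain it", {
  ds <- toy_dataset()
  # g12 occurs only in layer B; dropping layer A must not change its output
  m <- emgnn_model(model_config(f1_hidden = 8, f2_hidden = 8, seed = 3),
                   ncol(ds$X))
  y_full <- emgnn_forward(m, ds)
  ft <- feature_table(rownames(ds$X), colnames(ds$X), ds$X)
  ds_b <- multilayer_dataset(ds$layers[2], ft, ds$labels)
  y_b <- emgnn_forward(m, ds_b)
  expect_equal(y_b[["g12"]], y_full[["g12"]], tolerance = 1e-12)
})

test_that("count_parameters honors the sharing contract", {
  cfg <- model_config(f1_hidden = 16, f2_hidden = 16, seed = 1)
  m <- emgnn_model(cfg, 10)
  # parameter count is a function of config + d_in only, never of K: the
  # same model object runs unchanged on K=2 and K=6 datasets
  expect_equal(count_parameters(m), count_parameters(emgnn_model(cfg, 10)))
  m2 <- emgnn_model(model_config(f1_hidden = 32, f2_hidden = 16, seed = 1), 10)
  expect_gt(count_parameters(m2), count_parameters(m))
  # arithmetic oracle for the gcn parameterization:
  # f1: (d*h1 + h1) + (L1-1)*(h1*h1 + h1); proj: d*h1 + h1;
  # f2: h1*h2 + h2 + (L2-1)*(h2*h2 + h2); f3: h2*h2 + h2 + h2*2 + 2
  d <- 10; h1 <- 16; h2 <- 16
  expected <- (d * h1 + h1) + 2 * (h1 * h1 + h1) + (d * h1 + h1) +
    (h1 * h2 + h2) + (h2 * h2 + h2) + (h2 * 2 + 2)
  expect_equal(count_parameters(m), expected)
})

test_that("analytic gradients match numerical differentiation", {
  ds <- toy_dataset()
  lab_genes <- c(ds$labels$positives, ds$labels$negatives)
  idx <- match(lab_genes, ds$universe)
  y <- as.integer(lab_genes %in% ds$labels$positives)
  loss_of <- function(m, X = ds$X, w = NULL) {
    fw <- emgnn:::.emgnn_forward(m, ds, X = X, w = w)
    emgnn:::.ce_from_logits(fw$logits[idx, , drop = FALSE], y)
  }
  grads_of <- function(m, X = ds$X, w = NULL) {
    fw <- emgnn:::.emgnn_forward(m, ds, X = X, w = w)
    dl <- matrix(0, length(ds$universe), 2)
    dl[idx, ] <- (fw$prob[idx, , drop = FALSE] - cbind(1L - y, y)) / length(idx)
    emgnn:::.emgnn_backward(m, fw, dl, need_params = TRUE, need_x = TRUE,
                            need_w = TRUE)
  }
  eps <- 1e-6
  for (conv in c("gcn", "gat")) {
    cfg <- model_config(conv, f1_layers = 2, f1_hidden = 6, f2_layers = 2,
                        f2_hidden = 4, gat_heads = 2, dropout = 0, seed = 3)
    m <- emgnn_model(cfg, ncol(ds$X))
    g <- grads_of(m)
    # parameters: check a few coordinates of every parameter tensor
    for (path in list(c("f1", "1", "W"), c("f1", "2", "b"), c("proj", "W"),
                      c("f2", "1", "W"), c("f2", "2", "W"), c("f3", "W1"),
                      c("f3", "b2"))) {
      pick <- function(P) Reduce(function(o, k) {
        o[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
      }, path, P)
      arr <- pick(m$params); garr <- pick(g$params)
      for (ii in unique(pmin(length(arr), c(1L, 3L, length(arr))))) {
        bump <- function(v) {
          m2 <- m
          setr <- function(P, pth, val) {
            k <- if (grepl("^[0-9]+$", pth[1])) as.integer(pth[1]) else pth[1]
            if (length(pth) == 1L) { P[[k]] <- val; return(P) }
            P[[k]] <- setr(P[[k]], pth[-1], val)
            P
          }
          cur <- pick(m$params); cur[ii] <- cur[ii] + v
          m2$params <- setr(m$params, path, cur)
          m2
        }
        num <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
        expect_equal(garr[ii], num, tolerance = 1e-4)
      }
    }
    # input features
    for (ii in c(1L, 13L, 37L)) {
      Xp <- ds$X; Xp[ii] <- Xp[ii] + eps
      Xm <- ds$X; Xm[ii] <- Xm[ii] - eps
      num <- (loss_of(m, X = Xp) - loss_of(m, X = Xm)) / (2 * eps)
      expect_equal(g$dX[ii], num, tolerance = 1e-4)
    }
    # meta-edge weights
    w0 <- rep(0.7, ds$n_inst)
    gw <- grads_of(m, w = w0)
    for (ii in c(1L, 5L, 11L)) {
      wp <- w0; wp[ii] <- wp[ii] + eps
      wm <- w0; wm[ii] <- wm[ii] - eps
      num <- (loss_of(m, w = wp) - loss_of(m, w = wm)) / (2 * eps)
      expect_equal(gw$dw[ii], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip through save_emgnn/load_emgnn", {
  ds <- toy_dataset()
  m <- emgnn_model(model_config(f1_hidden = 8, f2_hidden = 8, seed = 9),
                   ncol(ds$X))
  m$trained <- TRUE
  f <- withr::local_tempfile(fileext = ".json")
  save_emgnn(m, f, universe = ds$universe)
  ck <- load_emgnn(f)
  expect_identical(ck$universe, ds$universe)
  expect_equal(emgnn_forward(ck$model, ds), emgnn_forward(m, ds),
               tolerance = 1e-12)
  expect_true(ck$model$trained)
})
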