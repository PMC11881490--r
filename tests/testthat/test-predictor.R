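# Tri-modal predictor: branch arithmetic, GAT behavior, training harness,
# ablations and thresholding.

ns <- asNamespace("hergforge")

test_that("vector branches reproduce a hand-computed two-layer forward", {
  set.seed(8)
  d_in <- 6L; hidden <- 5L
  bp <- ns$.mlp_branch_init(d_in, hidden, rng_make(3))
  st1 <- ns$.bn_state(hidden); st2 <- ns$.bn_state(hidden)
  st1$running_mean <- rnorm(hidden); st1$running_var <- runif(hidden, 0.5, 2)
  st2$running_mean <- rnorm(hidden); st2$running_var <- runif(hidden, 0.5, 2)
  x <- matrix(rnorm(2 * d_in), 2L)
  ns$ag_tape_begin()
  out <- ns$.branch_forward(ns$ag_const(x), bp, st1, st2, dropout = 0.5,
                            train = FALSE, rng = NULL)
  ns$ag_tape_end()
  # independent arithmetic (eval mode: running stats, no dropout)
  bn <- function(h, g, b, st) {
    t((t(h) - st$running_mean) / sqrt(st$running_var + 1e-5) *
        g[1, ] + b[1, ])
  }
  h1 <- x %*% bp$W1$val + rep(bp$b1$val[1, ], each = 2)
  h1 <- pmax(bn(h1, bp$g1$val, bp$be1$val, st1), 0)
  h2 <- h1 %*% bp$W2$val + rep(bp$b2$val[1, ], each = 2)
  h2 <- pmax(bn(h2, bp$g2$val, bp$be2$val, st2), 0)
  expect_lt(max(abs(out$val - h2)), 1e-5)
  expect_true(all(out$val >= 0))  # post-ReLU
})

test_that("the GAT convolution matches an explicit per-edge softmax oracle", {
  cfg <- hf_pred_config()
  dh <- cfg$gat_hidden %/% cfg$gat_heads
  layer <- ns$.gat_layer_init(14L, dh, cfg$gat_heads, rng_make(17))
  # 3-node path graph with simple features
  g <- build_graph("CCO")
  mask <- ns$.graph_mask(g)
  ns$ag_tape_begin()
  out <- ns$.gat_conv(ns$ag_const(g$node_features), layer, cfg$gat_heads,
                      dh, mask)
  ns$ag_tape_end()
  ref <- oracle_gat_conv(g$node_features, layer$W$val, layer$b$val[1, ],
                         lapply(layer$a_src, function(p) p$val[, 1]),
                         lapply(layer$a_dst, function(p) p$val[, 1]),
                         cfg$gat_heads, g$edges)
  expect_lt(max(abs(out$val - ref)), 1e-5)
})

test_that("graph encodings are invariant to node permutation (fuzz)", {
  cfg <- hf_pred_config()
  init <- ns$.predictor_init(cfg, 48L, 1024L, rng_make(23))
  smis <- hf_corpus()[seq(5, 100, by = 5)]
  for (s in smis) {
    g <- build_graph(s)
    n <- nrow(g$node_features)
    if (n < 2) next
    perm <- sample(n)
    inv <- order(perm)
    g2 <- g
    g2$node_features <- g$node_features[perm, , drop = FALSE]
    g2$edges <- matrix(inv[g$edges], ncol = 2L)
    ns$ag_tape_begin()
    v1 <- ns$.gat_forward(g, init$params, cfg)$val
    ns$ag_tape_end()
    ns$ag_tape_begin()
    v2 <- ns$.gat_forward(g2, init$params, cfg)$val
    ns$ag_tape_end()
    expect_lt(max(abs(v1 - v2)), 1e-8)
  }
})

test_that("a single-atom graph pools to its own layer-2 features", {
  cfg <- hf_pred_config()
  init <- ns$.predictor_init(cfg, 48L, 1024L, rng_make(29))
  g <- hf_quiet(build_graph("C"))
  expect_equal(nrow(g$node_features), 1L)
  dh <- cfg$gat_hidden %/% cfg$gat_heads
  ns$ag_tape_begin()
  pooled <- ns$.gat_forward(g, init$params, cfg)$val
  H <- ns$ag_const(g$node_features)
  mask <- ns$.graph_mask(g)
  h1 <- ns$ag_relu(ns$.gat_conv(H, init$params$gat1, cfg$gat_heads, dh,
                                mask))
  h2 <- ns$.gat_conv(h1, init$params$gat2, cfg$gat_heads, dh, mask)$val
  ns$ag_tape_end()
  expect_equal(pooled[1, ], h2[1, ], tolerance = 1e-10)
})

test_that("every branch combination trains and the fused width follows", {
  lab <- hf_labeled()[1:60, ]
  full_bundle <- featurize_for_predictor(lab$smiles, hf_featurizer(),
                                         hf_pred_config())
  combos <- expand.grid(tf = c(TRUE, FALSE), fp = c(TRUE, FALSE),
                        gr = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  for (k in seq_len(nrow(combos))) {
    cfg <- hf_pred_config("classification",
                          use_transformer = combos$tf[k],
                          use_fingerprint = combos$fp[k],
                          use_graph = combos$gr[k])
    m <- suppressMessages(fit_predictor(
      lab, if (combos$tf[k]) hf_featurizer() else NULL, cfg,
      train_recipe(epochs = 2L, batch_size = 16L), seed = 31,
      bundle = full_bundle))
    expected_in <- combos$tf[k] * cfg$branch_hidden +
      combos$fp[k] * cfg$branch_hidden + combos$gr[k] * cfg$gat_hidden
    expect_equal(nrow(m$params$fuse_W1$val), expected_in)
    pr <- predict(m, bundle_subset(full_bundle, 1:5))
    expect_length(pr, 5L)
    expect_true(all(pr >= 0 & pr <= 1))
  }
  expect_error(predictor_config(use_transformer = FALSE,
                                use_fingerprint = FALSE,
                                use_graph = FALSE), "at least one")
})

test_that("predictions are probabilities, deterministic, and thresholded", {
  reg <- hf_herg_regressor()
  smis <- hf_labeled()$smiles[1:20]
  p1 <- predict(reg, smis)
  p2 <- predict(reg, smis)
  expect_identical(p1, p2)
  labels <- classify_molecules(reg, smis)
  expect_identical(labels,
                   ifelse(p1 >= 5.0, "blocker", "non-blocker"))
  # boundary: a predicted pIC50 of exactly the threshold counts as blocker
  expect_identical(classify_molecules(reg, smis, threshold = min(p1)),
                   rep("blocker", 20L))
})

test_that("training refuses a single-class classification set", {
  lab <- hf_labeled()
  lab$blocker <- TRUE
  expect_error(
    suppressMessages(fit_predictor(lab[1:40, ], hf_featurizer(),
                                   hf_pred_config(), hf_recipe(2L),
                                   seed = 1)),
    "single class")
})

test_that("the L1 penalty shrinks weights toward zero", {
  lab <- hf_labeled()[1:80, ]
  cfg <- hf_pred_config("regression", use_transformer = FALSE,
                        use_graph = FALSE)
  median_w <- function(l1) {
    m <- fit_predictor(lab, NULL, cfg,
                       train_recipe(epochs = 8L, batch_size = 16L,
                                    l1_coeff = l1),
                       seed = 13)
    stats::median(abs(m$params$fp$W1$val))
  }
  expect_lt(median_w(0.05), median_w(0))
})

test_that("training loss decreases on a balanced toy set", {
  lab <- hf_labeled()[1:100, ]
  m <- suppressMessages(fit_predictor(lab, hf_featurizer(), hf_pred_config(),
                                      train_recipe(epochs = 10L,
                                                   batch_size = 32L),
                                      seed = 41))
  h <- m$history$train_loss
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
})
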