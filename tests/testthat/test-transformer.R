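# Transformer stacks: embedding composition, causality, oracle equivalence,
# feature extraction, training behavior, sampling and checkpointing.

ns <- asNamespace("hergforge")

toy_model <- function(n_blocks = 1L, n_heads = 1L, embed_dim = 8L,
                      max_content_len = 2L, vocab = NULL, seed = 5,
                      conditioned = FALSE) {
  if (is.null(vocab)) vocab <- build_vocabulary(c("CCO", "CCN", "CO"))
  cfg <- transformer_config(n_blocks, n_heads, embed_dim, max_content_len,
                            dropout = 0, ffn_mult = 2L)
  params <- ns$.tf_init(cfg, vocab, conditioned, rng_make(seed))
  list(cfg = cfg, params = params, vocab = vocab)
}

test_that("embeddings sum token, position, scaffold and property terms", {
  tm <- toy_model(embed_dim = 8L, max_content_len = 4L, conditioned = TRUE)
  v <- tm$vocab
  pad1 <- unname(v$token_to_id[[v$specials$pad]]) + 1L
  ids <- matrix(pad1, 1L, 6L)
  ns$ag_tape_begin()
  X <- ns$.tf_embed(tm$params, tm$cfg, ids)
  ns$ag_tape_end()
  expect_equal(dim(X$val), c(6L, 8L))
  # all-pad sequence without conditioning: rows are pad + position embedding
  expected <- tm$params$tok_emb$val[rep(pad1, 6L), ] +
    tm$params$pos_emb$val[1:6, ]
  expect_equal(X$val, expected, tolerance = 1e-12)

  # zero property vector and all-pad scaffold add the projection bias and
  # the pad-scaffold embedding on top of the unconditioned embedding
  ns$ag_tape_begin()
  Xc <- ns$.tf_embed(tm$params, tm$cfg, ids, scaffold_ids = ids,
                     prop = matrix(0, 1L, 10L))
  ns$ag_tape_end()
  delta <- Xc$val - X$val
  expected_delta <- matrix(tm$params$prop_b$val[1, ], 6L, 8L, byrow = TRUE) +
    tm$params$scaf_emb$val[rep(pad1, 6L), ]
  expect_equal(delta, expected_delta, tolerance = 1e-12)
})

test_that("decoder logits at position t ignore any suffix perturbation", {
  tm <- toy_model(n_blocks = 2L, n_heads = 2L, embed_dim = 8L,
                  max_content_len = 6L)
  V <- length(tm$vocab$token_to_id)
  ids <- matrix(sample(V, 8, replace = TRUE), 1L)
  mask <- ns$.tf_mask(1L, 8L, causal = TRUE)
  fwd <- function(ids) {
    ns$ag_tape_begin()
    X <- ns$.tf_embed(tm$params, tm$cfg, ids)
    out <- ns$.tf_stack(tm$params, tm$cfg, X, mask)
    ns$ag_tape_end()
    out$logits$val
  }
  base <- fwd(ids)
  for (t in 2:7) {
    pert <- ids
    pert[1, (t + 1L):8L] <- sample(V, 8L - t, replace = TRUE)
    new <- fwd(pert)
    expect_equal(new[1:t, ], base[1:t, ], tolerance = 1e-10)
  }
  expect_equal(dim(base), c(8L, V))
})

test_that("encoder attention is bidirectional", {
  tm <- toy_model(n_blocks = 1L, n_heads = 2L, embed_dim = 8L,
                  max_content_len = 6L)
  V <- length(tm$vocab$token_to_id)
  ids <- matrix(sample(V, 8, replace = TRUE), 1L)
  mask <- ns$.tf_mask(1L, 8L, causal = FALSE)
  fwd <- function(ids) {
    ns$ag_tape_begin()
    X <- ns$.tf_embed(tm$params, tm$cfg, ids)
    out <- ns$.tf_stack(tm$params, tm$cfg, X, mask)
    ns$ag_tape_end()
    out$states$val
  }
  base <- fwd(ids)
  pert <- ids
  pert[1, 8L] <- (ids[1, 8L]) %% V + 1L
  expect_gt(max(abs(fwd(pert)[1, ] - base[1, ])), 1e-8)
})

test_that("both stacks match a hand-rolled attention oracle", {
  for (spec in list(c(1L, 1L, 4L), c(2L, 2L, 8L))) {
    tm <- toy_model(n_blocks = spec[1], n_heads = spec[2],
                    embed_dim = spec[3], max_content_len = 4L, seed = 21)
    V <- length(tm$vocab$token_to_id)
    set.seed(33)
    ids <- matrix(sample(V, 6, replace = TRUE), 1L)
    pv <- oracle_param_values(tm$params)
    for (causal in c(TRUE, FALSE)) {
      mask <- ns$.tf_mask(1L, 6L, causal = causal)
      ns$ag_tape_begin()
      X <- ns$.tf_embed(tm$params, tm$cfg, ids)
      out <- ns$.tf_stack(tm$params, tm$cfg, X, mask)
      ns$ag_tape_end()
      ref <- oracle_transformer(pv, tm$cfg, ids[1, ], mask)
      expect_lt(max(abs(out$logits$val - ref$logits)), 1e-5)
      expect_lt(max(abs(out$states$val - ref$states)), 1e-5)
    }
  }
})

test_that("feature extraction is deterministic and molecule-specific", {
  enc <- hf_featurizer()
  f1 <- extract_feature(enc, c("CCO", "CCN"))
  expect_equal(dim(f1), c(2L, enc$config$embed_dim))
  f2 <- extract_feature(enc, "CCO")
  expect_identical(f1[1, ], f2[1, ])
  expect_gt(max(abs(f1[1, ] - f1[2, ])), 1e-8)
  expect_error(extract_feature(enc, "CCI"), "out-of-vocabulary")
  expect_error(extract_feature(hf_generator(), "CCO"), "bidirectional")
})

test_that("training reduces the loss and is reproducible for a fixed seed", {
  expect_lt(tail(hf_featurizer()$history, 1), hf_featurizer()$history[1])
  expect_lt(tail(hf_generator()$history, 1), hf_generator()$history[1])

  v <- build_vocabulary(c("CCO", "CCN", "COC"))
  tc <- preprocess_corpus(rep(c("CCO", "CCN", "COC"), 8), v,
                          max_content_len = 5L)
  cfg <- transformer_config(1L, 2L, 16L, 5L, ffn_mult = 2L)
  m1 <- fit_generator(tc, cfg, epochs = 2L, batch_size = 8L, seed = 9)
  m2 <- fit_generator(tc, cfg, epochs = 2L, batch_size = 8L, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$tok_emb$val, m2$params$tok_emb$val)
})

test_that("a decoder trained on one molecule memorizes it", {
  smi <- "CCOc1ccccc1"
  v <- build_vocabulary(smi)
  tc <- preprocess_corpus(rep(smi, 16), v, max_content_len = 14L)
  cfg <- transformer_config(1L, 2L, 24L, 14L, ffn_mult = 2L)
  gen <- fit_generator(tc, cfg, epochs = 150L, batch_size = 16L, lr = 3e-3,
                       seed = 4)
  expect_lt(tail(gen$history, 1), 0.1)  # near-zero per-token loss
  props <- as.numeric(physchem_properties(smi)[1, ])
  s <- sample_molecules(gen, murcko_scaffold(smi), props, n = 4L,
                        temperature = 0, rng = rng_make(2))
  expect_equal(unique(s$raw), smi)  # greedy limit is deterministic
})

test_that("sampled molecules all pass the validity filter", {
  gen <- hf_generator()
  props <- as.numeric(physchem_properties(hf_corpus()[1])[1, ])
  s <- hf_quiet(sample_molecules(gen, murcko_scaffold(hf_corpus()[1]),
                                 props, n = 24L, rng = rng_make(11)))
  expect_true(all(smiles_valid(s$smiles)))
  expect_gte(s$validity_rate, 0)
  expect_lte(s$validity_rate, 1)
})

test_that("checkpoints round-trip bit-identically", {
  enc <- hf_featurizer()
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  checkpoint_save(enc, tmp)
  enc2 <- checkpoint_load(tmp)
  expect_identical(extract_feature(enc, "CCO"), extract_feature(enc2, "CCO"))
  expect_identical(enc2$vocab$token_to_id, enc$vocab$token_to_id)
})

test_that("degenerate masking configuration is rejected before training", {
  expect_error(fit_featurizer(hf_tcorpus(), hf_tf_config(),
                              select_prob = 0), "select_prob")
})
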