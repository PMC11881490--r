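# Shared desk-scale fixtures, built once per test run and cached.
#
# Study conditions: a 300-molecule fragment-grammar corpus (content limit 36
# tokens), a 2-block / 4-head / 48-dim transformer pair, and planted-activity
# labels with the default coefficients. These sizes are the package's
# desk-scale reference conditions (see the methods vignette).

.hf_cache <- new.env(parent = emptyenv())

hf_get <- function(name, builder) {
  if (is.null(.hf_cache[[name]])) .hf_cache[[name]] <- builder()
  .hf_cache[[name]]
}

hf_corpus <- function() hf_get("corpus", function() {
  make_corpus(300, seed = 101)
})

hf_big_corpus <- function() hf_get("big_corpus", function() {
  make_corpus(1000, seed = 909)
})

hf_vocab <- function() hf_get("vocab", function() {
  build_vocabulary(hf_corpus())
})

hf_tcorpus <- function() hf_get("tcorpus", function() {
  suppressMessages(preprocess_corpus(hf_corpus(), hf_vocab(),
                                     max_content_len = 36L))
})

hf_tf_config <- function() {
  transformer_config(n_blocks = 2L, n_heads = 4L, embed_dim = 48L,
                     max_content_len = 36L, ffn_mult = 2L)
}

hf_featurizer <- function() hf_get("featurizer", function() {
  fit_featurizer(hf_tcorpus(), hf_tf_config(), epochs = 6L,
                 batch_size = 16L, seed = 202)
})

hf_generator <- function() hf_get("generator", function() {
  fit_generator(hf_tcorpus(), hf_tf_config(), epochs = 45L,
                batch_size = 16L, seed = 303)
})

hf_labeled <- function() hf_get("labeled", function() {
  lab <- make_labeled_set(hf_corpus(), seed = 404)
  lab[can_encode(hf_featurizer(), lab$smiles), , drop = FALSE]
})

hf_pred_config <- function(task = "classification", ...) {
  predictor_config(branch_hidden = 32L, gat_heads = 4L, gat_hidden = 32L,
                   fused_hidden = 64L, task = task, ...)
}

hf_recipe <- function(epochs = 25L) {
  train_recipe(epochs = epochs, batch_size = 32L)
}

# larger labeled set for the parameter-recovery and Y-randomization suites
hf_big_labeled_raw <- function() hf_get("big_labeled", function() {
  make_labeled_set(hf_big_corpus(), seed = 606)
})

hf_labeled_big <- function() hf_get("labeled_big", function() {
  lab <- hf_big_labeled_raw()
  lab <- lab[can_encode(hf_featurizer(), lab$smiles), , drop = FALSE]
  rownames(lab) <- NULL
  lab
})

# one shared tri-modal featurization of the big labeled set
hf_bundle_big <- function() hf_get("bundle_big", function() {
  featurize_for_predictor(hf_labeled_big()$smiles, hf_featurizer(),
                          hf_pred_config())
})

hf_herg_regressor <- function() hf_get("herg_regressor", function() {
  suppressMessages(fit_predictor(hf_labeled(), hf_featurizer(),
                                 hf_pred_config("regression"),
                                 hf_recipe(), seed = 505))
})

# quiet wrapper: OpenBabel chatters on stderr for exotic strings
hf_quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# re-engineering input: a basic-amine corpus molecule (the hERG-liability
# motif) with a productive generative neighborhood at desk scale
hf_pipeline_input <- function() "C1CCN(CCN(C)C)CC1"
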