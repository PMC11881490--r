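# Transformer models over SMILES token sequences: a scaffold- and
# property-conditioned autoregressive decoder for molecular generation, and
# a bidirectional masked-token encoder whose [CLS] state serves as a learned
# molecular feature vector.

#' Transformer architecture configuration
#'
#' Defaults mirror the full-scale recipe (8 pre-norm blocks, 8 heads,
#' embedding dimension 256, 10\% dropout, GeLU feed-forward); every field is
#' tunable so the same stack runs at desk scale.
#'
#' @param n_blocks Number of transformer blocks.
#' @param n_heads Attention heads; must divide `embed_dim`.
#' @param embed_dim Embedding dimension.
#' @param max_content_len Content tokens per sequence (block length is this
#'   plus the `[CLS]`/`[EOS]` specials).
#' @param dropout Dropout rate applied to embeddings and feed-forward
#'   layers.
#' @param ffn_mult Feed-forward hidden width as a multiple of `embed_dim`.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(n_blocks = 8L, n_heads = 8L, embed_dim = 256L,
                               max_content_len = 133L, dropout = 0.1,
                               ffn_mult = 4L) {
  stopifnot(n_blocks >= 1L, n_heads >= 1L, embed_dim %% n_heads == 0L,
            max_content_len >= 1L, dropout >= 0, dropout < 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim),
                 max_content_len = as.integer(max_content_len),
                 block_len = as.integer(max_content_len + 2L),
                 dropout = dropout, ffn_mult = as.integer(ffn_mult)),
            class = "transformer_config")
}

.tf_init <- function(config, vocab, conditioned, rng) {
  d <- config$embed_dim
  V <- vocab_size(vocab)
  Tn <- config$block_len
  p <- list(
    tok_emb = ag_param(init_matrix(rng, V, d, scale = 0.02)),
    pos_emb = ag_param(init_matrix(rng, Tn, d, scale = 0.02))
  )
  if (conditioned) {
    p$scaf_emb <- ag_param(init_matrix(rng, V, d, scale = 0.02))
    p$prop_W <- ag_param(init_matrix(rng, 10L, d))
    p$prop_b <- ag_param(matrix(0, 1L, d))
  }
  for (b in seq_len(config$n_blocks)) {
    blk <- list(
      ln1_g = ag_param(matrix(1, 1L, d)), ln1_b = ag_param(matrix(0, 1L, d)),
      Wq = ag_param(init_matrix(rng, d, d)), bq = ag_param(matrix(0, 1L, d)),
      Wk = ag_param(init_matrix(rng, d, d)), bk = ag_param(matrix(0, 1L, d)),
      Wv = ag_param(init_matrix(rng, d, d)), bv = ag_param(matrix(0, 1L, d)),
      Wo = ag_param(init_matrix(rng, d, d)), bo = ag_param(matrix(0, 1L, d)),
      ln2_g = ag_param(matrix(1, 1L, d)), ln2_b = ag_param(matrix(0, 1L, d)),
      W1 = ag_param(init_matrix(rng, d, d * config$ffn_mult)),
      b1 = ag_param(matrix(0, 1L, d * config$ffn_mult)),
      W2 = ag_param(init_matrix(rng, d * config$ffn_mult, d)),
      b2 = ag_param(matrix(0, 1L, d))
    )
    p[[paste0("block", b)]] <- blk
  }
  p$lnf_g <- ag_param(matrix(1, 1L, d))
  p$lnf_b <- ag_param(matrix(0, 1L, d))
  p$head_W <- ag_param(init_matrix(rng, d, V))
  p$head_b <- ag_param(matrix(0, 1L, V))
  p
}

.tf_param_list <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.environment(p[[nm]])) out[[nm]] <- p[[nm]]
    else out <- c(out, stats::setNames(p[[nm]],
                                       paste0(nm, ".", names(p[[nm]]))))
  }
  out
}

# Additive attention mask for a stacked batch: position (b,t) may attend to
# (b', t') iff b == b' and (not causal or t' <= t).
.tf_mask <- function(n_seq, t_len, causal) {
  n <- n_seq * t_len
  M <- matrix(-1e9, n, n)
  tri <- if (causal) {
    m <- matrix(-1e9, t_len, t_len)
    m[lower.tri(m, diag = TRUE)] <- 0
    m
  } else matrix(0, t_len, t_len)
  for (b in seq_len(n_seq)) {
    ix <- ((b - 1L) * t_len + 1L):(b * t_len)
    M[ix, ix] <- tri
  }
  M
}

# Sum token, position, and (optionally) scaffold + property embeddings.
# ids: n_seq x T integer matrix of 1-based token ids.
.tf_embed <- function(p, config, ids, scaffold_ids = NULL, prop = NULL,
                      train = FALSE, rng = NULL) {
  n_seq <- nrow(ids); Tn <- ncol(ids)
  if (Tn > config$block_len) {
    stop("sequence length ", Tn, " exceeds block length ", config$block_len)
  }
  flat <- as.integer(t(ids))           # row-major: seq 1 positions, seq 2, ...
  X <- ag_embed(p$tok_emb, flat)
  pos_idx <- rep(seq_len(Tn), n_seq)
  X <- ag_add(X, ag_embed(p$pos_emb, pos_idx))
  if (!is.null(scaffold_ids)) {
    sflat <- as.integer(t(scaffold_ids))
    X <- ag_add(X, ag_embed(p$scaf_emb, sflat))
  }
  if (!is.null(prop)) {
    pv <- ag_mm(ag_const(prop), p$prop_W)        # n_seq x d
    pv <- ag_add(pv, p$prop_b)
    X <- ag_add(X, ag_node(
      pv$val[rep(seq_len(n_seq), each = Tn), , drop = FALSE],
      list(pv),
      local({
        n_seq_c <- n_seq; Tn_c <- Tn
        function(g) .acc(pv, rowsum(g, rep(seq_len(n_seq_c), each = Tn_c)))
      })))
  }
  ag_dropout(X, config$dropout, train, rng)
}

# Pre-norm block stack; returns list(states = post-final-LN hidden states,
# logits = vocabulary logits).
.tf_stack <- function(p, config, X, mask, train = FALSE, rng = NULL) {
  d <- config$embed_dim
  nh <- config$n_heads
  dh <- d %/% nh
  for (b in seq_len(config$n_blocks)) {
    blk <- p[[paste0("block", b)]]
    Xn <- ag_layernorm(X, blk$ln1_g, blk$ln1_b)
    Q <- ag_add(ag_mm(Xn, blk$Wq), blk$bq)
    K <- ag_add(ag_mm(Xn, blk$Wk), blk$bk)
    V <- ag_add(ag_mm(Xn, blk$Wv), blk$bv)
    heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- ag_node(Q$val[, cols, drop = FALSE], list(Q), local({
        cc <- cols
        function(g) {
          gf <- matrix(0, nrow(Q$val), ncol(Q$val)); gf[, cc] <- g
          .acc(Q, gf)
        }
      }))
      Kh <- ag_node(K$val[, cols, drop = FALSE], list(K), local({
        cc <- cols
        function(g) {
          gf <- matrix(0, nrow(K$val), ncol(K$val)); gf[, cc] <- g
          .acc(K, gf)
        }
      }))
      Vh <- ag_node(V$val[, cols, drop = FALSE], list(V), local({
        cc <- cols
        function(g) {
          gf <- matrix(0, nrow(V$val), ncol(V$val)); gf[, cc] <- g
          .acc(V, gf)
        }
      }))
      S <- ag_scale(ag_mm(Qh, ag_transpose(Kh)), 1 / sqrt(dh))
      A <- ag_softmax_rows(S, mask)
      heads[[h]] <- ag_mm(A, Vh)
    }
    H <- ag_concat_cols(heads)
    att <- ag_add(ag_mm(H, blk$Wo), blk$bo)
    X <- ag_add(X, att)
    Xn2 <- ag_layernorm(X, blk$ln2_g, blk$ln2_b)
    F1 <- ag_gelu(ag_add(ag_mm(Xn2, blk$W1), blk$b1))
    F1 <- ag_dropout(F1, config$dropout, train, rng)
    F2 <- ag_add(ag_mm(F1, blk$W2), blk$b2)
    X <- ag_add(X, F2)
  }
  states <- ag_layernorm(X, p$lnf_g, p$lnf_b)
  logits <- ag_add(ag_mm(states, p$head_W), p$head_b)
  list(states = states, logits = logits)
}

ag_transpose <- function(a) {
  ag_node(t(a$val), list(a), function(g) .acc(a, t(g)))
}

.tf_prop_stats <- function(prop_mat) {
  mu <- colMeans(prop_mat)
  sd <- apply(prop_mat, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

.tf_normalize_props <- function(prop_mat, stats) {
  sweep(sweep(as.matrix(prop_mat), 2L, stats$mean), 2L, stats$sd, "/")
}

# Tokenize scaffolds under the shared vocabulary; empty scaffolds become
# all-pad rows so acyclic molecules condition on "no scaffold". A canonical
# scaffold can occasionally be longer than its parent molecule or use
# tokens outside the vocabulary; such scaffolds also fall back to the
# all-pad (absent) row.
.tf_scaffold_ids <- function(scaffolds, vocab, max_content_len) {
  sp <- special_ids(vocab)
  pad_row <- rep(sp[["pad"]], max_content_len + 2L)
  t(vapply(scaffolds, function(s) {
    if (!nzchar(s)) return(pad_row)
    tryCatch(encode_sequence(s, vocab, max_content_len),
             error = function(e) pad_row)
  }, integer(max_content_len + 2L)))
}

#' Fit the conditioned autoregressive SMILES generator
#'
#' Trains a causal transformer for next-token prediction on a processed
#' corpus, conditioning every sequence on its own Murcko scaffold (embedded
#' with a separate table and summed position-wise) and its ten
#' physicochemical properties (z-scored, linearly projected to the embedding
#' dimension and broadcast). Cross entropy excludes padding positions;
#' optimization is AdamW; the returned model carries the final-epoch
#' weights.
#'
#' @param corpus A `token_corpus` from [preprocess_corpus()].
#' @param config A [transformer_config()].
#' @param epochs,batch_size,lr,weight_decay Training hyperparameters
#'   (full-scale defaults: 100 epochs, batch 512, lr 3e-4, weight decay
#'   0.1).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param verbose Print per-epoch loss?
#' @return A `herg_transformer` object (kind `"decoder"`).
#' @export
fit_generator <- function(corpus, config = transformer_config(),
                          epochs = 100L, batch_size = 512L, lr = 3e-4,
                          weight_decay = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(corpus, "token_corpus"))
  if (nrow(corpus$ids) == 0L) stop("empty corpus")
  if (config$max_content_len != corpus$max_content_len) {
    stop("config max_content_len (", config$max_content_len,
         ") != corpus (", corpus$max_content_len, ")")
  }
  scaffolds <- murcko_scaffold(corpus$smiles)
  scaf_ids <- .tf_scaffold_ids(scaffolds, corpus$vocab,
                               corpus$max_content_len)
  props <- as.matrix(physchem_properties(corpus$smiles))
  prop_stats <- .tf_prop_stats(props)
  propn <- .tf_normalize_props(props, prop_stats)
  model <- .tf_train(corpus, config, epochs, batch_size, lr, weight_decay,
                     seed, verbose, kind = "decoder",
                     scaf_ids = scaf_ids, propn = propn)
  model$prop_stats <- prop_stats
  model
}

#' Fit the bidirectional masked-token featurizer
#'
#' Trains an unconditioned, bidirectional transformer for masked-token
#' recovery: each content token is selected with probability
#' `select_prob`, and selected tokens are replaced by `<MASK>` / a random
#' token / left unchanged in the proportions `mask_frac` /`random_frac` /
#' the remainder. Cross entropy is computed only at selected positions.
#' After training, [extract_feature()] reads the `[CLS]`-position state from
#' the penultimate layer (after the final layer normalization, before the
#' vocabulary projection) as a fixed-length molecular embedding.
#'
#' @inheritParams fit_generator
#' @param select_prob,mask_frac,random_frac Masking scheme (defaults 0.15,
#'   0.8, 0.1; the remaining 0.1 keeps the token unchanged).
#' @return A `herg_transformer` object (kind `"encoder"`).
#' @export
fit_featurizer <- function(corpus, config = transformer_config(),
                           epochs = 100L, batch_size = 512L, lr = 3e-4,
                           weight_decay = 0.1, select_prob = 0.15,
                           mask_frac = 0.8, random_frac = 0.1, seed = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(corpus, "token_corpus"))
  if (nrow(corpus$ids) == 0L) stop("empty corpus")
  if (select_prob <= 0) {
    stop("select_prob must be positive: no position would contribute loss")
  }
  .tf_train(corpus, config, epochs, batch_size, lr, weight_decay, seed,
            verbose, kind = "encoder", select_prob = select_prob,
            mask_frac = mask_frac, random_frac = random_frac)
}

.tf_train <- function(corpus, config, epochs, batch_size, lr, weight_decay,
                      seed, verbose, kind, scaf_ids = NULL, propn = NULL,
                      select_prob = 0.15, mask_frac = 0.8,
                      random_frac = 0.1) {
  rng <- rng_make(seed)
  vocab <- corpus$vocab
  p <- .tf_init(config, vocab, conditioned = (kind == "decoder"), rng)
  plist <- .tf_param_list(p)
  opt <- adamw_make(plist, lr = lr, weight_decay = weight_decay)
  n <- nrow(corpus$ids)
  bs <- min(batch_size, n)
  sp <- special_ids(vocab)
  masks <- list()  # cached per batch size
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- rng_sample(rng, n, n)
    n_batch <- max(1L, n %/% bs)
    ep_loss <- 0; ep_w <- 0
    for (bi in seq_len(n_batch)) {
      ix <- ord[((bi - 1L) * bs + 1L):min(bi * bs, n)]
      ids <- corpus$ids[ix, , drop = FALSE] + 1L  # to 1-based
      nb <- nrow(ids)
      key <- as.character(nb)
      if (is.null(masks[[key]])) {
        masks[[key]] <- .tf_mask(nb, config$block_len, kind == "decoder")
      }
      l <- NULL
      ag_tape_begin()
      if (kind == "decoder") {
        X <- .tf_embed(p, config, ids,
                       scaffold_ids = scaf_ids[ix, , drop = FALSE] + 1L,
                       prop = propn[ix, , drop = FALSE], train = TRUE,
                       rng = rng)
        out <- .tf_stack(p, config, X, masks[[key]], train = TRUE,
                         rng = rng)
        # next-token targets; weight 0 on pads-as-target and the final slot
        flat <- as.integer(t(ids))
        tgt <- rep(1L, length(flat))
        w <- numeric(length(flat))
        Tn <- config$block_len
        for (r in seq_len(nb)) {
          rows <- ((r - 1L) * Tn + 1L):(r * Tn)
          tgt[rows[-Tn]] <- flat[rows[-1L]]
          w[rows[-Tn]] <- as.numeric(flat[rows[-1L]] != sp[["pad"]] + 1L)
        }
        l <- ag_cross_entropy(out$logits, tgt, w)
      } else {
        corrupted <- ids
        w <- numeric(length(ids))
        tgt <- as.integer(t(ids))
        Tn <- config$block_len
        for (r in seq_len(nb)) {
          mk <- apply_masking(ids[r, ] - 1L, vocab,
                              select_prob = select_prob,
                              mask_frac = mask_frac,
                              random_frac = random_frac,
                              keep_frac = 1 - mask_frac - random_frac,
                              rng = rng)
          corrupted[r, ] <- mk$corrupted + 1L
          w[((r - 1L) * Tn + 1L):(r * Tn)] <- as.numeric(mk$loss_mask)
        }
        if (sum(w) > 0) {
          X <- .tf_embed(p, config, corrupted, train = TRUE, rng = rng)
          out <- .tf_stack(p, config, X, masks[[key]], train = TRUE,
                           rng = rng)
          l <- ag_cross_entropy(out$logits, tgt, w)
        }
      }
      if (is.null(l)) {
        ag_tape_end()
        next
      }
      ag_backward(l)
      ag_tape_end()
      adamw_step(opt)
      ag_zero_grads(plist)
      ep_loss <- ep_loss + l$val[1, 1] * nb
      ep_w <- ep_w + nb
    }
    history[ep] <- ep_loss / max(ep_w, 1)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f", ep, history[ep]))
    }
  }
  structure(list(params = p, config = config, vocab = vocab, kind = kind,
                 prop_stats = NULL, history = history, seed = seed),
            class = "herg_transformer")
}

#' @export
print.herg_transformer <- function(x, ...) {
  cat("SMILES transformer (", x$kind, "): ", x$config$n_blocks, " blocks, ",
      x$config$n_heads, " heads, dim ", x$config$embed_dim,
      ", block length ", x$config$block_len, "\n", sep = "")
  if (length(x$history)) {
    cat("final training loss:", round(utils::tail(x$history, 1), 4), "over",
        length(x$history), "epochs\n")
  }
  invisible(x)
}

#' Can these SMILES be encoded under a model's vocabulary and block length?
#'
#' @param model A `herg_transformer`.
#' @param smiles Character vector.
#' @return Logical vector; FALSE for strings with out-of-vocabulary tokens
#'   or more content tokens than the model's block accommodates.
#' @export
can_encode <- function(model, smiles) {
  vapply(smiles, function(s) {
    toks <- tryCatch(smi_tokenize(s), error = function(e) NULL)
    if (is.null(toks)) return(FALSE)
    if (length(toks) > model$config$max_content_len) return(FALSE)
    !anyNA(encode_tokens(toks, model$vocab))
  }, logical(1), USE.NAMES = FALSE)
}

#' Extract the transformer feature vector of a molecule
#'
#' Runs the bidirectional featurizer in evaluation mode (dropout disabled)
#' and returns the hidden state at the `[CLS]` position after the final
#' layer normalization, immediately before the vocabulary projection.
#'
#' @param model A `herg_transformer` of kind `"encoder"`.
#' @param smiles One or more SMILES strings (must tokenize under the
#'   model's vocabulary).
#' @return Numeric matrix, one row per molecule, `embed_dim` columns.
#' @export
extract_feature <- function(model, smiles) {
  stopifnot(inherits(model, "herg_transformer"))
  if (model$kind != "encoder") {
    stop("feature extraction requires the bidirectional encoder")
  }
  ids <- t(vapply(smiles, encode_sequence, vocab = model$vocab,
                  max_content_len = model$config$max_content_len,
                  integer(model$config$block_len))) + 1L
  out <- matrix(0, length(smiles), model$config$embed_dim)
  # batch to keep the dense attention matrix small
  bs <- max(1L, 512L %/% model$config$block_len)
  for (start in seq(1L, length(smiles), by = bs)) {
    ix <- start:min(start + bs - 1L, length(smiles))
    mask <- .tf_mask(length(ix), model$config$block_len, causal = FALSE)
    ag_tape_begin()
    X <- .tf_embed(model$params, model$config, ids[ix, , drop = FALSE])
    res <- .tf_stack(model$params, model$config, X, mask)
    ag_tape_end()
    cls_rows <- (seq_along(ix) - 1L) * model$config$block_len + 1L
    out[ix, ] <- res$states$val[cls_rows, , drop = FALSE]
  }
  out
}

#' Sample molecules from the trained generator
#'
#' Autoregressively samples token sequences conditioned on a scaffold and a
#' ten-property target vector, starting from `[CLS]` and stopping at `[EOS]`
#' or the block limit, then keeps only strings that parse as valid
#' molecules.
#'
#' @param model A `herg_transformer` of kind `"decoder"`.
#' @param scaffold Scaffold SMILES ("" for none).
#' @param properties Numeric vector of the ten conditioning properties, in
#'   [PHYSCHEM_NAMES] order (raw scale; normalization uses the statistics
#'   stored in the model).
#' @param n Number of sequences to draw.
#' @param temperature Softmax temperature (0 = greedy argmax).
#' @param top_k Optional top-k truncation of the proposal distribution.
#' @param rng Random stream from [rng_make()].
#' @return List with `smiles` (valid unique-draw strings, one per sampled
#'   sequence that parsed), `raw` (all decoded strings) and `validity_rate`.
#' @export
sample_molecules <- function(model, scaffold, properties, n = 32L,
                             temperature = 1.0, top_k = NULL,
                             rng = rng_make(1L)) {
  stopifnot(inherits(model, "herg_transformer"))
  if (model$kind != "decoder") stop("sampling requires the decoder")
  if (length(properties) != 10L) stop("need exactly 10 properties")
  vocab <- model$vocab
  sp <- special_ids(vocab)
  Tn <- model$config$block_len
  scaf_row <- .tf_scaffold_ids(scaffold, vocab,
                               model$config$max_content_len)[1L, ] + 1L
  propn <- .tf_normalize_props(matrix(as.numeric(properties), 1L),
                               model$prop_stats)
  id_to_token <- names(vocab$token_to_id)
  seqs <- matrix(sp[["pad"]] + 1L, n, Tn)
  seqs[, 1L] <- sp[["cls"]] + 1L
  alive <- rep(TRUE, n)
  scaf_mat <- matrix(scaf_row, n, Tn, byrow = TRUE)
  prop_mat <- propn[rep(1L, n), , drop = FALSE]
  for (t in seq_len(Tn - 1L)) {
    if (!any(alive)) break
    act <- which(alive)
    # forward only the generated prefix; causal attention makes the logits
    # at position t identical to a full-block forward
    mask <- .tf_mask(length(act), t, causal = TRUE)
    ag_tape_begin()
    X <- .tf_embed(model$params, model$config,
                   seqs[act, seq_len(t), drop = FALSE],
                   scaffold_ids = scaf_mat[act, seq_len(t), drop = FALSE],
                   prop = prop_mat[act, , drop = FALSE])
    out <- .tf_stack(model$params, model$config, X, mask)
    ag_tape_end()
    rows <- seq_along(act) * t
    logits <- out$logits$val[rows, , drop = FALSE]
    logits[, sp[["pad"]] + 1L] <- -Inf
    logits[, sp[["cls"]] + 1L] <- -Inf
    logits[, sp[["mask"]] + 1L] <- -Inf
    for (r in seq_along(act)) {
      lg <- logits[r, ]
      nxt <- if (temperature <= 0) {
        which.max(lg)
      } else {
        z <- lg / temperature
        if (!is.null(top_k)) {
          cutoff <- sort(z, decreasing = TRUE)[min(top_k, sum(is.finite(z)))]
          z[z < cutoff] <- -Inf
        }
        z <- z - max(z)
        pr <- exp(z); pr <- pr / sum(pr)
        u <- rng_runif(rng, 1L)
        findInterval(u, cumsum(pr)) + 1L
      }
      seqs[act[r], t + 1L] <- nxt
      if (nxt == sp[["eos"]] + 1L) alive[act[r]] <- FALSE
    }
  }
  decode <- function(row) {
    toks <- id_to_token[row]
    body <- character(0)
    for (k in 2L:length(toks)) {
      if (toks[k] %in% unlist(vocab$specials)) break
      body <- c(body, toks[k])
    }
    paste0(body, collapse = "")
  }
  raw <- apply(seqs, 1L, decode)
  nonempty <- nzchar(raw)
  valid <- nonempty
  valid[nonempty] <- smiles_valid(raw[nonempty])
  list(smiles = raw[valid], raw = raw, validity_rate = mean(valid))
}

#' Save or load a transformer / predictor checkpoint
#'
#' Checkpoints are self-contained: weights, configuration, vocabulary and
#' property-normalization statistics travel together, so loading requires
#' no other file.
#'
#' @param model A `herg_transformer` or `herg_predictor`.
#' @param path File path.
#' @return `checkpoint_load` returns the restored object.
#' @export
checkpoint_save <- function(model, path) {
  strip <- function(x) {
    if (is.environment(x)) {
      as.list(x)[c("val")]
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  obj <- model
  obj$params <- strip(model$params)
  if (!is.null(model$bn_states)) {
    obj$bn_states <- lapply(model$bn_states, function(s) {
      list(running_mean = s$running_mean, running_var = s$running_var)
    })
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) {
  obj <- readRDS(path)
  revive <- function(x) {
    if (is.list(x) && identical(names(x), "val")) {
      ag_param(x$val)
    } else if (is.list(x)) {
      lapply(x, revive)
    } else x
  }
  obj$params <- revive(obj$params)
  if (!is.null(obj$bn_states)) {
    obj$bn_states <- lapply(obj$bn_states, function(s) {
      env <- new.env(parent = emptyenv())
      env$running_mean <- s$running_mean
      env$running_var <- s$running_var
      env
    })
  }
  obj
}
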