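# Tri-modal cardiac ion-channel activity predictors: a transformer-derived
# feature vector, an ECFP4 fingerprint and a molecular graph are encoded by
# separate branches (two-layer batch-norm MLPs; a two-layer graph attention
# network with global add pooling), concatenated, and mapped to a blocker
# probability (classification) or a predicted pIC50 (regression).

#' Predictor architecture configuration
#'
#' @param use_transformer,use_fingerprint,use_graph Enable each feature
#'   branch (all three is the shipped default; any non-empty subset
#'   trains, mirroring the ablation harness).
#' @param branch_hidden Hidden width of the vector branches.
#' @param gat_heads,gat_hidden Attention heads and total hidden width of the
#'   GAT branch (`gat_hidden` must be divisible by `gat_heads`).
#' @param fused_hidden Hidden width of the fusion head.
#' @param dropout Dropout rate in all fully connected components.
#' @param task `"classification"` or `"regression"`.
#' @param channel Channel tag (`"hERG"`, `"NaV1.5"`, `"CaV1.2"`).
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(use_transformer = TRUE, use_fingerprint = TRUE,
                             use_graph = TRUE, branch_hidden = 128L,
                             gat_heads = 8L, gat_hidden = 64L,
                             fused_hidden = 256L, dropout = 0.5,
                             task = c("classification", "regression"),
                             channel = "hERG") {
  task <- match.arg(task)
  if (!any(use_transformer, use_fingerprint, use_graph)) {
    stop("at least one feature branch must be enabled")
  }
  stopifnot(gat_hidden %% gat_heads == 0L, dropout >= 0, dropout < 1)
  structure(list(use_transformer = use_transformer,
                 use_fingerprint = use_fingerprint,
                 use_graph = use_graph,
                 branch_hidden = as.integer(branch_hidden),
                 gat_heads = as.integer(gat_heads),
                 gat_hidden = as.integer(gat_hidden),
                 fused_hidden = as.integer(fused_hidden),
                 dropout = dropout, task = task, channel = channel),
            class = "predictor_config")
}

#' Aggregate replicate pIC50 measurements
#'
#' Collapses replicate measurements for one compound to a single label:
#' values above the replicate set's 95th percentile are discarded as high
#' outliers and the rest are averaged. A single replicate is returned
#' unchanged.
#'
#' @param values Numeric vector of replicate pIC50 values.
#' @return Aggregated pIC50.
#' @export
aggregate_labels <- function(values) {
  if (length(values) == 0L) stop("no replicate values supplied")
  if (length(values) == 1L) return(values)
  q <- stats::quantile(values, 0.95, names = FALSE)
  mean(values[values <= q])
}

# ---- featurization bundle ----

#' Featurize molecules for the tri-modal predictor
#'
#' Computes whichever of the three representations the branches need:
#' transformer `[CLS]` features (via `featurizer`), 1024-bit ECFP4
#' fingerprints and molecular graphs.
#'
#' @param smiles Character vector.
#' @param featurizer A trained `herg_transformer` encoder (or NULL when the
#'   transformer branch is disabled).
#' @param config A `predictor_config`.
#' @return List with `tf`, `fp` (matrices or NULL) and `graphs` (list or
#'   NULL), plus the canonical input `smiles`.
#' @export
featurize_for_predictor <- function(smiles, featurizer, config) {
  tf <- if (config$use_transformer) {
    if (is.null(featurizer)) stop("transformer branch enabled but no featurizer given")
    extract_feature(featurizer, smiles)
  } else NULL
  fp <- if (config$use_fingerprint) ecfp4(smiles) else NULL
  graphs <- if (config$use_graph) lapply(smiles, build_graph) else NULL
  list(smiles = smiles, tf = tf, fp = fp, graphs = graphs)
}

#' Subset a feature bundle by molecule index
#'
#' @param bundle A bundle from [featurize_for_predictor()].
#' @param ix Integer indices.
#' @return A bundle restricted to the selected molecules.
#' @export
bundle_subset <- function(bundle, ix) {
  list(smiles = bundle$smiles[ix],
       tf = if (!is.null(bundle$tf)) bundle$tf[ix, , drop = FALSE],
       fp = if (!is.null(bundle$fp)) bundle$fp[ix, , drop = FALSE],
       graphs = if (!is.null(bundle$graphs)) bundle$graphs[ix])
}

# ---- parameter construction ----

.mlp_branch_init <- function(d_in, hidden, rng) {
  list(W1 = ag_param(init_matrix(rng, d_in, hidden)),
       b1 = ag_param(matrix(0, 1L, hidden)),
       g1 = ag_param(matrix(1, 1L, hidden)),
       be1 = ag_param(matrix(0, 1L, hidden)),
       W2 = ag_param(init_matrix(rng, hidden, hidden)),
       b2 = ag_param(matrix(0, 1L, hidden)),
       g2 = ag_param(matrix(1, 1L, hidden)),
       be2 = ag_param(matrix(0, 1L, hidden)))
}

.gat_layer_init <- function(d_in, dh, heads, rng) {
  list(W = ag_param(init_matrix(rng, d_in, dh * heads)),
       b = ag_param(matrix(0, 1L, dh * heads)),
       a_src = lapply(seq_len(heads), function(h)
         ag_param(init_matrix(rng, dh, 1L))),
       a_dst = lapply(seq_len(heads), function(h)
         ag_param(init_matrix(rng, dh, 1L))))
}

.bn_state <- function(d) {
  env <- new.env(parent = emptyenv())
  env$running_mean <- rep(0, d)
  env$running_var <- rep(1, d)
  env
}

.predictor_init <- function(config, tf_dim, fp_bits, rng) {
  p <- list()
  st <- list()
  fused_in <- 0L
  if (config$use_transformer) {
    p$tf <- .mlp_branch_init(tf_dim, config$branch_hidden, rng)
    st$tf1 <- .bn_state(config$branch_hidden)
    st$tf2 <- .bn_state(config$branch_hidden)
    fused_in <- fused_in + config$branch_hidden
  }
  if (config$use_fingerprint) {
    p$fp <- .mlp_branch_init(fp_bits, config$branch_hidden, rng)
    st$fp1 <- .bn_state(config$branch_hidden)
    st$fp2 <- .bn_state(config$branch_hidden)
    fused_in <- fused_in + config$branch_hidden
  }
  if (config$use_graph) {
    dh <- config$gat_hidden %/% config$gat_heads
    p$gat1 <- .gat_layer_init(14L, dh, config$gat_heads, rng)
    p$gat2 <- .gat_layer_init(config$gat_hidden, dh, config$gat_heads, rng)
    fused_in <- fused_in + config$gat_hidden
  }
  p$fuse_W1 <- ag_param(init_matrix(rng, fused_in, config$fused_hidden))
  p$fuse_b1 <- ag_param(matrix(0, 1L, config$fused_hidden))
  p$fuse_g <- ag_param(matrix(1, 1L, config$fused_hidden))
  p$fuse_be <- ag_param(matrix(0, 1L, config$fused_hidden))
  st$fuse <- .bn_state(config$fused_hidden)
  p$out_W <- ag_param(init_matrix(rng, config$fused_hidden, 1L))
  p$out_b <- ag_param(matrix(0, 1L, 1L))
  list(params = p, bn_states = st, fused_in = fused_in)
}

.flatten_params <- function(x, prefix = "") {
  out <- list()
  if (is.environment(x)) {
    out[[prefix]] <- x
  } else if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    for (k in seq_along(x)) {
      out <- c(out, .flatten_params(x[[k]], paste0(prefix, ".", nms[k])))
    }
  }
  out
}

# ---- forward passes ----

# Two-layer (linear -> batch-norm -> ReLU -> dropout) encoder for a plain
# feature matrix.
.branch_forward <- function(x, bp, st1, st2, dropout, train, rng) {
  h <- ag_add(ag_mm(x, bp$W1), bp$b1)
  h <- ag_batchnorm(h, bp$g1, bp$be1, st1, train)
  h <- ag_dropout(ag_relu(h), dropout, train, rng)
  h <- ag_add(ag_mm(h, bp$W2), bp$b2)
  h <- ag_batchnorm(h, bp$g2, bp$be2, st2, train)
  ag_dropout(ag_relu(h), dropout, train, rng)
}

# One multi-head GAT convolution over a dense neighborhood mask (self-loops
# included); heads are concatenated.
.gat_conv <- function(H, layer, heads, dh, mask) {
  Z <- ag_add(ag_mm(H, layer$W), layer$b)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Zh <- ag_node(Z$val[, cols, drop = FALSE], list(Z), local({
      cc <- cols
      function(g) {
        gf <- matrix(0, nrow(Z$val), ncol(Z$val)); gf[, cc] <- g
        .acc(Z, gf)
      }
    }))
    s <- ag_mm(Zh, layer$a_src[[h]])
    t <- ag_mm(Zh, layer$a_dst[[h]])
    E <- ag_leaky_relu(ag_outer_add(s, t))
    A <- ag_softmax_rows(E, mask)
    outs[[h]] <- ag_mm(A, Zh)
  }
  ag_concat_cols(outs)
}

# Dense neighborhood mask with self-loops: 0 where j is i or bonded to i,
# -1e9 elsewhere.
.graph_mask <- function(graph) {
  n <- nrow(graph$node_features)
  M <- matrix(-1e9, n, n)
  diag(M) <- 0
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
      M[i, j] <- 0; M[j, i] <- 0
    }
  }
  M
}

# Encode a batch of molecular graphs: nodes are stacked into one matrix
# and attention runs under a block-diagonal neighborhood mask, so the
# per-graph computation is identical to running each graph alone.
.gat_forward_batch <- function(graphs, p, config) {
  dh <- config$gat_hidden %/% config$gat_heads
  ns <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offsets <- cumsum(c(0L, ns[-length(ns)]))
  total <- sum(ns)
  mask <- matrix(-1e9, total, total)
  for (k in seq_along(graphs)) {
    ix <- (offsets[k] + 1L):(offsets[k] + ns[k])
    mask[ix, ix] <- .graph_mask(graphs[[k]])
  }
  H <- ag_const(do.call(rbind, lapply(graphs, function(g) g$node_features)))
  H1 <- ag_relu(.gat_conv(H, p$gat1, config$gat_heads, dh, mask))
  H2 <- .gat_conv(H1, p$gat2, config$gat_heads, dh, mask)
  ag_pool_rows(H2, rep(seq_along(graphs), ns))
}

# Encode one molecular graph to a 1 x gat_hidden vector.
.gat_forward <- function(graph, p, config) {
  .gat_forward_batch(list(graph), p, config)
}

# Full fused forward pass for a feature bundle subset `ix`; returns the
# output node (n x 1 raw score).
.predictor_forward <- function(model, bundle, ix, train = FALSE,
                               rng = NULL) {
  config <- model$config
  p <- model$params
  st <- model$bn_states
  parts <- list()
  if (config$use_transformer) {
    parts <- c(parts, list(.branch_forward(
      ag_const(bundle$tf[ix, , drop = FALSE]), p$tf, st$tf1, st$tf2,
      config$dropout, train, rng)))
  }
  if (config$use_fingerprint) {
    parts <- c(parts, list(.branch_forward(
      ag_const(bundle$fp[ix, , drop = FALSE]), p$fp, st$fp1, st$fp2,
      config$dropout, train, rng)))
  }
  if (config$use_graph) {
    # chunk the graph batch: the dense block-diagonal mask grows
    # quadratically with stacked node count
    chunks <- split(seq_along(ix), ceiling(seq_along(ix) / 8L))
    gparts <- lapply(chunks, function(ch) {
      .gat_forward_batch(bundle$graphs[ix[ch]], p, config)
    })
    parts <- c(parts, list(if (length(gparts) == 1L) gparts[[1L]]
                           else ag_concat_rows(gparts)))
  }
  fused <- if (length(parts) == 1L) parts[[1L]] else ag_concat_cols(parts)
  h <- ag_add(ag_mm(fused, p$fuse_W1), p$fuse_b1)
  h <- ag_batchnorm(h, p$fuse_g, p$fuse_be, st$fuse, train)
  h <- ag_dropout(ag_relu(h), config$dropout, train, rng)
  ag_add(ag_mm(h, p$out_W), p$out_b)
}

# ---- training ----

#' Training recipe for the discriminative models
#'
#' Defaults follow the full-scale recipe: AdamW (lr 3e-4, weight decay
#' 1e-4), L1 coefficient 1e-4, batch size 32, gradient clipping at norm
#' 5.0, learning-rate halving after 10 epochs without validation
#' improvement, 200 epochs for classification and 100 for regression, and
#' snapshot selection by best validation accuracy (classification) or
#' Pearson correlation (regression).
#'
#' @param epochs Number of epochs (if NULL: 200 for classification, 100 for
#'   regression).
#' @param batch_size,lr,weight_decay,l1_coeff,plateau_patience,grad_clip
#'   Optimization settings.
#' @param val_frac Fraction of records held out for validation-based
#'   selection.
#' @return A `train_recipe` list.
#' @export
train_recipe <- function(epochs = NULL, batch_size = 32L, lr = 3e-4,
                         weight_decay = 1e-4, l1_coeff = 1e-4,
                         plateau_patience = 10L, grad_clip = 5.0,
                         val_frac = 0.2) {
  stopifnot(batch_size >= 2L, lr > 0, weight_decay >= 0, l1_coeff >= 0,
            plateau_patience >= 1L, grad_clip > 0, val_frac > 0,
            val_frac < 1)
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, l1_coeff = l1_coeff,
                 plateau_patience = as.integer(plateau_patience),
                 grad_clip = grad_clip, val_frac = val_frac),
            class = "train_recipe")
}

#' Fit a cardiac ion-channel activity predictor
#'
#' Trains the tri-modal architecture on labeled molecules. Records need a
#' `smiles` column and a `pic50` column (classification labels are derived
#' as pIC50 >= 5.0 unless a logical/0-1 `blocker` column is supplied).
#' The loss is binary cross entropy (classification) or mean squared error
#' (regression) plus an L1 penalty on all weights; the returned model
#' carries the parameter snapshot from the epoch with the best validation
#' accuracy or Pearson correlation.
#'
#' @param records Data.frame of training records.
#' @param featurizer Trained `herg_transformer` encoder (required when the
#'   transformer branch is enabled).
#' @param config A [predictor_config()].
#' @param recipe A [train_recipe()].
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress?
#' @param bundle Optional precomputed feature bundle from
#'   [featurize_for_predictor()], row-aligned with `records` (skips
#'   refeaturization; no encodability filtering is applied).
#' @return A `herg_predictor` object.
#' @export
fit_predictor <- function(records, featurizer = NULL,
                          config = predictor_config(),
                          recipe = train_recipe(), seed = 1L,
                          verbose = FALSE, bundle = NULL) {
  stopifnot(is.data.frame(records), "smiles" %in% names(records))
  task <- config$task
  y <- if (task == "classification") {
    if ("blocker" %in% names(records)) as.numeric(records$blocker)
    else if ("pic50" %in% names(records)) as.numeric(records$pic50 >= 5.0)
    else stop("classification needs a 'blocker' or 'pic50' column")
  } else {
    if (!"pic50" %in% names(records)) stop("regression needs a 'pic50' column")
    as.numeric(records$pic50)
  }
  if (config$use_transformer && is.null(bundle)) {
    if (is.null(featurizer)) stop("transformer branch enabled but no featurizer given")
    enc_ok <- can_encode(featurizer, records$smiles)
    if (!all(enc_ok)) {
      message(sum(!enc_ok), " record(s) dropped: not encodable under the ",
              "featurizer vocabulary/block length")
      records <- records[enc_ok, , drop = FALSE]
      y <- y[enc_ok]
    }
  }
  if (!is.null(bundle) && length(bundle$smiles) != nrow(records)) {
    stop("'bundle' is not row-aligned with 'records'")
  }
  n <- nrow(records)
  if (n < 5L) stop("too few usable records (", n, ")")
  epochs <- recipe$epochs
  if (is.null(epochs)) epochs <- if (task == "classification") 200L else 100L
  rng <- rng_make(seed)
  # validation split
  n_val <- max(1L, round(n * recipe$val_frac))
  perm <- rng_sample(rng, n, n)
  val_ix <- perm[seq_len(n_val)]
  tr_ix <- perm[(n_val + 1L):n]
  if (task == "classification" &&
      (length(unique(y[tr_ix])) < 2L)) {
    stop("training set contains a single class; cannot fit a classifier")
  }
  if (is.null(bundle)) {
    bundle <- featurize_for_predictor(records$smiles, featurizer, config)
  }
  tf_dim <- if (config$use_transformer) ncol(bundle$tf) else 0L
  fp_bits <- if (config$use_fingerprint) ncol(bundle$fp) else 0L
  init <- .predictor_init(config, tf_dim, fp_bits, rng)
  # initialize the output bias at the training base rate / label mean so the
  # network starts from the marginal prediction and learns residuals
  init$params$out_b$val[1, 1] <- if (task == "classification") {
    stats::qlogis(min(max(mean(y[tr_ix]), 0.05), 0.95))
  } else {
    mean(y[tr_ix])
  }
  model <- structure(
    list(params = init$params, bn_states = init$bn_states, config = config,
         recipe = recipe, seed = seed, featurizer = featurizer,
         history = NULL),
    class = "herg_predictor")
  plist <- .flatten_params(init$params)
  opt <- adamw_make(plist, lr = recipe$lr,
                    weight_decay = recipe$weight_decay)
  bs <- min(recipe$batch_size, length(tr_ix))
  best_metric <- -Inf
  best_snapshot <- NULL
  best_bn <- NULL
  since_improve <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_metric = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- tr_ix[rng_sample(rng, length(tr_ix), length(tr_ix))]
    n_batch <- max(1L, length(ord) %/% bs)
    ep_loss <- 0; ep_n <- 0
    for (bi in seq_len(n_batch)) {
      ix <- ord[((bi - 1L) * bs + 1L):min(bi * bs, length(ord))]
      ag_tape_begin()
      out <- .predictor_forward(model, bundle, ix, train = TRUE, rng = rng)
      l <- if (task == "classification") ag_bce_with_logits(out, y[ix])
           else ag_mse_loss(out, y[ix])
      ag_backward(l)
      ag_tape_end()
      adamw_step(opt, grad_clip = recipe$grad_clip, l1 = recipe$l1_coeff)
      ag_zero_grads(plist)
      ep_loss <- ep_loss + l$val[1, 1] * length(ix)
      ep_n <- ep_n + length(ix)
    }
    # validation metric in eval mode
    val_pred <- .predict_scores(model, bundle, val_ix)
    val_metric <- if (task == "classification") {
      mean((val_pred >= 0.5) == (y[val_ix] >= 0.5))
    } else {
      if (stats::sd(val_pred) == 0 || stats::sd(y[val_ix]) == 0) 0
      else stats::cor(val_pred, y[val_ix])
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                   val_metric = val_metric))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f", ep,
                      ep_loss / ep_n, val_metric))
    }
    if (val_metric > best_metric + 1e-12) {
      best_metric <- val_metric
      best_snapshot <- lapply(plist, function(p) p$val)
      best_bn <- lapply(model$bn_states, function(s) {
        list(running_mean = s$running_mean, running_var = s$running_var)
      })
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= recipe$plateau_patience) {
        opt$lr <- opt$lr / 2
        since_improve <- 0L
      }
    }
  }
  if (!is.null(best_snapshot)) {
    for (nm in names(plist)) plist[[nm]]$val <- best_snapshot[[nm]]
    for (nm in names(model$bn_states)) {
      model$bn_states[[nm]]$running_mean <- best_bn[[nm]]$running_mean
      model$bn_states[[nm]]$running_var <- best_bn[[nm]]$running_var
    }
  }
  model$history <- hist
  model$best_val_metric <- best_metric
  model$val_ix <- val_ix
  model
}

# Eval-mode scores (probabilities for classification, pIC50 for
# regression) for a subset of a feature bundle.
.predict_scores <- function(model, bundle, ix) {
  out <- numeric(length(ix))
  bs <- 64L
  for (start in seq(1L, length(ix), by = bs)) {
    sub <- ix[start:min(start + bs - 1L, length(ix))]
    ag_tape_begin()
    o <- .predictor_forward(model, bundle, sub, train = FALSE)
    ag_tape_end()
    z <- o$val[, 1L]
    out[start:(start + length(sub) - 1L)] <-
      if (model$config$task == "classification") 1 / (1 + exp(-z)) else z
  }
  out
}

#' @export
print.herg_predictor <- function(x, ...) {
  branches <- c(if (x$config$use_transformer) "transformer",
                if (x$config$use_fingerprint) "fingerprint",
                if (x$config$use_graph) "graph")
  cat("Cardiac channel predictor (", x$config$channel, ", ", x$config$task,
      ")\n  branches: ", paste(branches, collapse = " + "), "\n", sep = "")
  if (!is.null(x$best_val_metric)) {
    cat("  best validation metric:", round(x$best_val_metric, 4), "\n")
  }
  invisible(x)
}

#' Predict channel activity for new molecules
#'
#' @param object A `herg_predictor`.
#' @param newdata Character vector of SMILES, or a feature bundle from
#'   [featurize_for_predictor()].
#' @param ... Unused.
#' @return Numeric vector: blocker probabilities (classification) or
#'   predicted pIC50 values (regression).
#' @export
predict.herg_predictor <- function(object, newdata, ...) {
  bundle <- if (is.character(newdata)) {
    featurize_for_predictor(newdata, object$featurizer, object$config)
  } else newdata
  n <- length(bundle$smiles)
  .predict_scores(object, bundle, seq_len(n))
}

#' Classify molecules as channel blockers
#'
#' Regression models are thresholded at `threshold` (pIC50 >= threshold is
#' a blocker); classification models are thresholded at probability 0.5.
#'
#' @param model A `herg_predictor`.
#' @param smiles SMILES strings or a feature bundle.
#' @param threshold pIC50 blocker threshold (default 5.0).
#' @return Character vector `"blocker"` / `"non-blocker"`.
#' @export
classify_molecules <- function(model, smiles, threshold = 5.0) {
  scores <- predict(model, smiles)
  hit <- if (model$config$task == "regression") scores >= threshold
         else scores >= 0.5
  ifelse(hit, "blocker", "non-blocker")
}
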