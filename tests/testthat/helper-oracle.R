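# Independent plain-matrix oracles used to cross-check the model stacks.
# These are written directly from the architecture description (pre-norm
# blocks, scaled dot-product attention, per-edge softmax attention) and
# share no code with the package's autodiff implementation.

oracle_layernorm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  va <- rowMeans((x - mu)^2)
  ((x - mu) / sqrt(va + eps)) * rep(g, each = nrow(x)) +
    rep(b, each = nrow(x))
}

oracle_softmax_masked <- function(x, mask) {
  x <- x + mask
  t(apply(x, 1, function(r) {
    e <- exp(r - max(r))
    e / sum(e)
  }))
}

oracle_gelu <- function(x) x * pnorm(x)

# One pre-norm transformer block, explicit per-head computation.
oracle_block <- function(X, blk, n_heads, mask) {
  d <- ncol(X)
  dh <- d / n_heads
  Xn <- oracle_layernorm(X, blk$ln1_g, blk$ln1_b)
  Q <- Xn %*% blk$Wq + rep(blk$bq, each = nrow(X))
  K <- Xn %*% blk$Wk + rep(blk$bk, each = nrow(X))
  V <- Xn %*% blk$Wv + rep(blk$bv, each = nrow(X))
  heads <- NULL
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    A <- oracle_softmax_masked(S, mask)
    heads <- cbind(heads, A %*% V[, cols, drop = FALSE])
  }
  X <- X + heads %*% blk$Wo + rep(blk$bo, each = nrow(X))
  Xn2 <- oracle_layernorm(X, blk$ln2_g, blk$ln2_b)
  F1 <- oracle_gelu(Xn2 %*% blk$W1 + rep(blk$b1, each = nrow(X)))
  X + F1 %*% blk$W2 + rep(blk$b2, each = nrow(X))
}

# Extract plain numeric values from a model's parameter environments.
oracle_param_values <- function(params) {
  grab <- function(x) {
    if (is.environment(x)) x$val
    else if (is.list(x)) lapply(x, grab)
    else x
  }
  grab(params)
}

# Full stack: embeddings (no dropout), blocks, final layernorm, logits.
oracle_transformer <- function(pv, config, ids_row, mask) {
  Tn <- length(ids_row)
  X <- pv$tok_emb[ids_row, , drop = FALSE] +
    pv$pos_emb[seq_len(Tn), , drop = FALSE]
  for (b in seq_len(config$n_blocks)) {
    blk <- pv[[paste0("block", b)]]
    blk$ln1_g <- blk$ln1_g[1, ]; blk$ln1_b <- blk$ln1_b[1, ]
    blk$ln2_g <- blk$ln2_g[1, ]; blk$ln2_b <- blk$ln2_b[1, ]
    blk$bq <- blk$bq[1, ]; blk$bk <- blk$bk[1, ]; blk$bv <- blk$bv[1, ]
    blk$bo <- blk$bo[1, ]; blk$b1 <- blk$b1[1, ]; blk$b2 <- blk$b2[1, ]
    X <- oracle_block(X, blk, config$n_heads, mask)
  }
  states <- oracle_layernorm(X, pv$lnf_g[1, ], pv$lnf_b[1, ])
  list(states = states,
       logits = states %*% pv$head_W + rep(pv$head_b[1, ], each = Tn))
}

# Explicit per-edge GAT convolution on one graph (self-loops included).
oracle_gat_conv <- function(H, Wv, bv, a_src, a_dst, heads, edges) {
  n <- nrow(H)
  dtot <- ncol(Wv)
  dh <- dtot / heads
  Z <- H %*% Wv + rep(bv, each = n)
  nbr <- lapply(seq_len(n), function(i) i)  # self-loops
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  out <- matrix(0, n, dtot)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Zh <- Z[, cols, drop = FALSE]
    for (i in seq_len(n)) {
      js <- nbr[[i]]
      e <- vapply(js, function(j) {
        lrelu(sum(Zh[i, ] * a_src[[h]]) + sum(Zh[j, ] * a_dst[[h]]))
      }, numeric(1))
      a <- exp(e - max(e)); a <- a / sum(a)
      out[i, cols] <- colSums(a * Zh[js, , drop = FALSE])
    }
  }
  out
}

# Brute-force normalized mutual information between all column pairs,
# using its textbook definition on already-binned columns.
oracle_nmi_matrix <- function(binned) {
  p <- length(binned)
  H <- function(b) {
    pr <- table(b) / length(b)
    -sum(pr * log(pr))
  }
  M <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    joint <- table(binned[[i]], binned[[j]]) / length(binned[[i]])
    px <- rowSums(joint); py <- colSums(joint)
    mi <- 0
    for (a in seq_len(nrow(joint))) for (b in seq_len(ncol(joint))) {
      if (joint[a, b] > 0) {
        mi <- mi + joint[a, b] * log(joint[a, b] / (px[a] * py[b]))
      }
    }
    hi <- H(binned[[i]]); hj <- H(binned[[j]])
    M[i, j] <- if (hi == 0 || hj == 0) 1 else mi / sqrt(hi * hj)
  }
  M
}

# All-pairs AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
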