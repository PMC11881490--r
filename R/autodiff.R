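# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A "node" is an environment holding $val (matrix), $grad (accumulated
# gradient, lazily initialized), $parents and $bw (a closure that pushes the
# node's gradient to its parents). Nodes created while a tape is active are
# recorded in creation order; ag_backward() walks the tape in reverse.
# Parameters are nodes that live outside any tape and persist across steps.
#
# This is deliberately small: just the operations needed by the transformer
# stacks, the GAT encoder and the feed-forward heads, each with a
# numerically checked backward pass (see the gradient-check tests).

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_begin <- function() {
  .ag$tape <- new.env(parent = emptyenv())
  .ag$tape$nodes <- vector("list", 256L)
  .ag$tape$n <- 0L
  invisible(.ag$tape)
}

ag_tape_end <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

.ag_record <- function(node) {
  tp <- .ag$tape
  if (!is.null(tp)) {
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) {
      tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    }
    tp$nodes[[tp$n]] <- node
  }
  node
}

ag_node <- function(val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  .ag_record(nd)
}

# A parameter: persistent node, never taped.
ag_param <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- if (is.matrix(val)) val else matrix(val, nrow = 1L)
  nd$grad <- NULL
  nd$parents <- list()
  nd$bw <- NULL
  nd$is_param <- TRUE
  nd
}

ag_const <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- if (is.matrix(val)) val else matrix(val, nrow = 1L)
  nd$grad <- NULL
  nd$parents <- list()
  nd$bw <- NULL
  nd$is_const <- TRUE
  nd
}

.acc <- function(node, g) {
  if (isTRUE(node$is_const)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ag_backward <- function(loss) {
  tp <- .ag$tape
  if (is.null(tp)) stop("no active tape")
  loss$grad <- matrix(1, 1, 1)
  for (k in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[k]]
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- operations ----

ag_mm <- function(a, b) {
  v <- a$val %*% b$val
  ag_node(v, list(a, b), function(g) {
    .acc(a, g %*% t(b$val))
    .acc(b, t(a$val) %*% g)
  })
}

# a + b; b may be a 1-row bias broadcast over a's rows.
ag_add <- function(a, b) {
  broadcast <- nrow(b$val) == 1L && nrow(a$val) > 1L
  v <- if (broadcast) sweep(a$val, 2L, b$val[1L, ], "+") else a$val + b$val
  ag_node(v, list(a, b), function(g) {
    .acc(a, g)
    .acc(b, if (broadcast) matrix(colSums(g), 1L) else g)
  })
}

ag_mul <- function(a, b) {
  v <- a$val * b$val
  ag_node(v, list(a, b), function(g) {
    .acc(a, g * b$val)
    .acc(b, g * a$val)
  })
}

ag_scale <- function(a, s) {
  ag_node(a$val * s, list(a), function(g) .acc(a, g * s))
}

ag_relu <- function(a) {
  pos <- a$val > 0
  ag_node(a$val * pos, list(a), function(g) .acc(a, g * pos))
}

ag_leaky_relu <- function(a, slope = 0.2) {
  f <- slope + (1 - slope) * (a$val > 0)
  ag_node(a$val * f, list(a), function(g) .acc(a, g * f))
}

ag_gelu <- function(a) {
  x <- a$val
  v <- x * stats::pnorm(x)
  ag_node(v, list(a), function(g) {
    .acc(a, g * (stats::pnorm(x) + x * stats::dnorm(x)))
  })
}

ag_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$val))
  ag_node(v, list(a), function(g) .acc(a, g * v * (1 - v)))
}

# Inverted dropout; draws from an explicit random stream.
ag_dropout <- function(a, p, train, rng = NULL) {
  if (!train || p <= 0) return(a)
  u <- if (is.null(rng)) stats::runif(length(a$val))
       else rng_runif(rng, length(a$val))
  mask <- matrix(u >= p, nrow(a$val)) / (1 - p)
  v <- a$val * mask
  ag_node(v, list(a), function(g) .acc(a, g * mask))
}

# Row-wise layer normalization with learnable gain/bias (1 x d each).
ag_layernorm <- function(a, gain, bias, eps = 1e-5) {
  x <- a$val
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2L, gain$val[1L, ], "*"), 2L, bias$val[1L, ], "+")
  ag_node(v, list(a, gain, bias), function(g) {
    .acc(gain, matrix(colSums(g * xhat), 1L))
    .acc(bias, matrix(colSums(g), 1L))
    gx <- sweep(g, 2L, gain$val[1L, ], "*")
    d <- ncol(x)
    rs1 <- rowSums(gx)
    rs2 <- rowSums(gx * xhat)
    .acc(a, inv * (gx - rs1 / d - xhat * rs2 / d))
  })
}

# Row-wise softmax with an optional additive mask (plain matrix, e.g. -1e9
# at disallowed positions).
ag_softmax_rows <- function(a, mask = NULL) {
  x <- a$val
  if (!is.null(mask)) x <- x + mask
  rmax <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - rmax)
  v <- e / rowSums(e)
  ag_node(v, list(a), function(g) {
    .acc(a, (g - rowSums(g * v)) * v)
  })
}

# Gather rows of an embedding table (1-based indices).
ag_embed <- function(table, idx) {
  v <- table$val[idx, , drop = FALSE]
  ag_node(v, list(table), function(g) {
    agg <- rowsum(g, group = idx)
    rows <- as.integer(rownames(agg))
    gfull <- matrix(0, nrow(table$val), ncol(table$val))
    gfull[rows, ] <- agg
    .acc(table, gfull)
  })
}

# Select rows (indices must be unique).
ag_slice_rows <- function(a, idx) {
  v <- a$val[idx, , drop = FALSE]
  ag_node(v, list(a), function(g) {
    gfull <- matrix(0, nrow(a$val), ncol(a$val))
    gfull[idx, ] <- g
    .acc(a, gfull)
  })
}

ag_concat_cols <- function(parts) {
  v <- do.call(cbind, lapply(parts, function(p) p$val))
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(v, parts, function(g) {
    for (k in seq_along(parts)) {
      .acc(parts[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

ag_concat_rows <- function(parts) {
  v <- do.call(rbind, lapply(parts, function(p) p$val))
  heights <- vapply(parts, function(p) nrow(p$val), integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(v, parts, function(g) {
    for (k in seq_along(parts)) {
      .acc(parts[[k]], g[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

# Column-vector s (n x 1) + row-vector t (m x 1) -> n x m outer sum.
ag_outer_add <- function(s, t) {
  v <- matrix(s$val[, 1L], nrow(s$val), nrow(t$val)) +
    matrix(t$val[, 1L], nrow(s$val), nrow(t$val), byrow = TRUE)
  ag_node(v, list(s, t), function(g) {
    .acc(s, matrix(rowSums(g), ncol = 1L))
    .acc(t, matrix(colSums(g), ncol = 1L))
  })
}

# Segment-sum rows by integer group (global add pooling over a batch of
# stacked graphs); groups must be 1..k and the output row order is group
# order.
ag_pool_rows <- function(a, groups) {
  gi <- as.integer(groups)
  v <- rowsum(a$val, gi, reorder = TRUE)
  ag_node(v, list(a), function(g) {
    .acc(a, g[gi, , drop = FALSE])
  })
}

# Sum all rows into a single row vector (global add pooling).
ag_sum_rows <- function(a) {
  v <- matrix(colSums(a$val), 1L)
  ag_node(v, list(a), function(g) {
    .acc(a, matrix(g[1L, ], nrow(a$val), ncol(a$val), byrow = TRUE))
  })
}

# Column-wise batch normalization. `state` is an environment carrying
# running_mean / running_var (updated in train mode, used in eval mode).
ag_batchnorm <- function(a, gamma, beta, state, train, momentum = 0.1,
                         eps = 1e-5) {
  x <- a$val
  n <- nrow(x)
  if (train && n > 1L) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    va <- colMeans(xc^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    uva <- va * n / max(n - 1L, 1L)
    state$running_var <- (1 - momentum) * state$running_var + momentum * uva
    inv <- 1 / sqrt(va + eps)
    xhat <- sweep(xc, 2L, inv, "*")
    v <- sweep(sweep(xhat, 2L, gamma$val[1L, ], "*"), 2L, beta$val[1L, ], "+")
    ag_node(v, list(a, gamma, beta), function(g) {
      .acc(gamma, matrix(colSums(g * xhat), 1L))
      .acc(beta, matrix(colSums(g), 1L))
      gx <- sweep(g, 2L, gamma$val[1L, ], "*")
      cs1 <- colSums(gx)
      cs2 <- colSums(gx * xhat)
      dx <- sweep(gx, 2L, cs1 / n) - sweep(xhat, 2L, cs2 / n, "*")
      .acc(a, sweep(dx, 2L, inv, "*"))
    })
  } else {
    inv <- 1 / sqrt(state$running_var + eps)
    xhat <- sweep(sweep(x, 2L, state$running_mean), 2L, inv, "*")
    v <- sweep(sweep(xhat, 2L, gamma$val[1L, ], "*"), 2L, beta$val[1L, ], "+")
    ag_node(v, list(a, gamma, beta), function(g) {
      .acc(gamma, matrix(colSums(g * xhat), 1L))
      .acc(beta, matrix(colSums(g), 1L))
      .acc(a, sweep(sweep(g, 2L, gamma$val[1L, ], "*"), 2L, inv, "*"))
    })
  }
}

## ---- losses ----

# Cross entropy over rows of `logits` against integer targets (1-based);
# `weight` is a 0/1 vector selecting the rows that contribute.
ag_cross_entropy <- function(logits, targets, weight) {
  x <- logits$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  w <- as.numeric(weight)
  sw <- sum(w)
  if (sw == 0) stop("cross entropy: no positions selected by the loss mask")
  picked <- p[cbind(seq_len(nrow(p)), targets)]
  v <- matrix(-sum(w * log(pmax(picked, 1e-12))) / sw, 1L, 1L)
  ag_node(v, list(logits), function(g) {
    gl <- p
    gl[cbind(seq_len(nrow(p)), targets)] <-
      gl[cbind(seq_len(nrow(p)), targets)] - 1
    .acc(logits, gl * (w / sw) * g[1L, 1L])
  })
}

ag_bce_with_logits <- function(logits, y) {
  z <- logits$val[, 1L]
  y <- as.numeric(y)
  p <- 1 / (1 + exp(-z))
  n <- length(z)
  v <- matrix(-mean(y * log(pmax(p, 1e-12)) +
                    (1 - y) * log(pmax(1 - p, 1e-12))), 1L, 1L)
  ag_node(v, list(logits), function(g) {
    .acc(logits, matrix((p - y) / n, ncol = 1L) * g[1L, 1L])
  })
}

ag_mse_loss <- function(pred, y) {
  d <- pred$val[, 1L] - as.numeric(y)
  n <- length(d)
  v <- matrix(mean(d^2), 1L, 1L)
  ag_node(v, list(pred), function(g) {
    .acc(pred, matrix(2 * d / n, ncol = 1L) * g[1L, 1L])
  })
}

## ---- optimizer ----

# AdamW with optional global-norm gradient clipping and an L1 subgradient
# term added to the raw gradients.
adamw_make <- function(params, lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2
  opt$eps <- eps; opt$wd <- weight_decay
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$val * 0)
  opt$v <- lapply(params, function(p) p$val * 0)
  opt
}

adamw_step <- function(opt, grad_clip = NULL, l1 = 0) {
  grads <- lapply(opt$params, function(p) {
    g <- if (is.null(p$grad)) p$val * 0 else p$grad
    if (l1 > 0) g <- g + l1 * sign(p$val)
    g
  })
  if (!is.null(grad_clip)) {
    total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (is.finite(total) && total > grad_clip) {
      grads <- lapply(grads, function(g) g * (grad_clip / total))
    }
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in seq_along(opt$params)) {
    p <- opt$params[[k]]
    g <- grads[[k]]
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    p$val <- p$val - opt$lr * (mhat / (sqrt(vhat) + opt$eps) +
                               opt$wd * p$val)
  }
  invisible(opt)
}

# Kaiming/Xavier-style initialization drawn from an explicit stream.
init_matrix <- function(rng, n_in, n_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (n_in + n_out))
  matrix(rng_rnorm(rng, n_in * n_out, sd = scale), n_in, n_out)
}
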