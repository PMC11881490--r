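# The end-to-end re-engineering workflow: conditioned generation around an
# input molecule's scaffold and properties, per-channel activity filtering,
# descriptor-space pruning + cosine ranking, and a PCA chemical-space
# projection for visual inspection.

#' Per-channel activity constraint
#'
#' Two modes mirror the filtering options of the workflow: `"range"` keeps
#' candidates whose predicted pIC50 satisfies `min_pic50 <= p < max_pic50`
#' (the upper bound is strict, so a filter at 6.0 excludes predictions >=
#' 6.0); `"nonblocker"` keeps candidates a classification model scores
#' below probability 0.5.
#'
#' @param channel Channel name; must match a name in the predictor list
#'   handed to [reengineer()].
#' @param max_pic50,min_pic50 pIC50 bounds for range mode.
#' @param mode `"range"` or `"nonblocker"`.
#' @return A `channel_constraint` object.
#' @export
channel_constraint <- function(channel, max_pic50 = Inf, min_pic50 = -Inf,
                               mode = c("range", "nonblocker")) {
  mode <- match.arg(mode)
  if (mode == "range" && !(min_pic50 < max_pic50)) {
    stop("range mode needs min_pic50 < max_pic50")
  }
  structure(list(channel = channel, mode = mode, low = min_pic50,
                 high = max_pic50),
            class = "channel_constraint")
}

#' Improvement-by-k-log-units constraint
#'
#' Convenience wrapper expressing "change the channel activity by at least
#' `magnitude` log units relative to the input molecule's predicted value"
#' as a range constraint.
#'
#' @param channel Channel name.
#' @param input_pic50 The input molecule's predicted pIC50 for the channel.
#' @param direction `"decrease"` (upper bound) or `"increase"` (lower
#'   bound).
#' @param magnitude Log-unit shift (default 1 = tenfold).
#' @return A `channel_constraint`.
#' @export
improvement_constraint <- function(channel, input_pic50,
                                   direction = c("decrease", "increase"),
                                   magnitude = 1) {
  direction <- match.arg(direction)
  if (direction == "decrease") {
    channel_constraint(channel, max_pic50 = input_pic50 - magnitude)
  } else {
    channel_constraint(channel, min_pic50 = input_pic50 + magnitude)
  }
}

#' Test per-channel predictions against a constraint set
#'
#' @param predictions Named list/vector: predicted pIC50 (range mode) or
#'   blocker probability (nonblocker mode) per channel.
#' @param constraints List of [channel_constraint()] objects (conjunction).
#' @return TRUE iff every constraint accepts.
#' @export
apply_constraints <- function(predictions, constraints) {
  for (ct in constraints) {
    if (!ct$channel %in% names(predictions)) {
      stop("no prediction available for channel ", ct$channel)
    }
    p <- as.numeric(predictions[[ct$channel]])
    ok <- if (ct$mode == "range") (p >= ct$low) && (p < ct$high)
          else p < 0.5
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Rank candidate molecules by cosine similarity to the input
#'
#' Operates on the pruned, standardized descriptor block: descending cosine
#' similarity to the input vector, ties broken by lexicographic canonical
#' SMILES order.
#'
#' @param input_vec Input molecule's descriptor vector (already masked /
#'   standardized).
#' @param cand_mat Candidate descriptor matrix (same columns).
#' @param cand_smiles Canonical SMILES per candidate row (for tie-breaks).
#' @return Data.frame with `rank`, `smiles`, `similarity`.
#' @export
rank_candidates <- function(input_vec, cand_mat, cand_smiles) {
  stopifnot(nrow(cand_mat) == length(cand_smiles))
  sims <- vapply(seq_len(nrow(cand_mat)), function(i) {
    cosine_similarity(input_vec, cand_mat[i, ])
  }, numeric(1))
  ord <- order(-sims, cand_smiles)
  data.frame(rank = seq_along(ord), smiles = cand_smiles[ord],
             similarity = sims[ord], stringsAsFactors = FALSE)
}

#' Chemical-space PCA projection
#'
#' Projects input, candidates and a background corpus sample into the first
#' two principal components of the standardized 10-property space.
#'
#' @param input_smiles Single SMILES string.
#' @param candidate_smiles Character vector.
#' @param background_smiles Character vector (e.g. a sample of the
#'   generator's training corpus).
#' @return List with `coords` (data.frame: smiles, group, PC1, PC2) and
#'   `explained_variance` (fractions for PC1, PC2).
#' @export
chem_space_projection <- function(input_smiles, candidate_smiles,
                                  background_smiles) {
  all_smiles <- c(input_smiles, candidate_smiles, background_smiles)
  if (length(all_smiles) < 3L) stop("need at least 3 molecules")
  group <- c("input", rep("candidate", length(candidate_smiles)),
             rep("background", length(background_smiles)))
  props <- as.matrix(physchem_properties(all_smiles))
  keep <- apply(props, 2, function(x) stats::sd(x) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant property column(s) dropped from the PCA")
  }
  props <- props[, keep, drop = FALSE]
  pc <- stats::prcomp(props, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = data.frame(smiles = all_smiles, group = group,
                           PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                           stringsAsFactors = FALSE),
       explained_variance = ev[1:2])
}

#' Re-engineer a molecule for desired cardiac channel activity
#'
#' Runs the full workflow: compute the input molecule's Murcko scaffold and
#' ten physicochemical properties; repeatedly sample the conditioned
#' generator; keep valid, unique molecules (the input itself is excluded)
#' whose per-channel predictions satisfy every constraint; stop at
#' `n_candidates` accepted or the attempt cap; then build descriptor
#' vectors for input plus candidates, z-score each column, drop redundant
#' descriptors by pairwise mutual information, and rank candidates by
#' cosine similarity to the input.
#'
#' @param input_smiles The hERG-active (or otherwise flagged) input
#'   molecule.
#' @param constraints List of [channel_constraint()] objects.
#' @param generator Trained decoder (`herg_transformer`).
#' @param predictors Named list of `herg_predictor` objects keyed by
#'   channel (each constraint's channel must be present).
#' @param n_candidates Number of accepted candidates requested.
#' @param seed Integer seed (generation is deterministic given seed and
#'   checkpoints).
#' @param batch_size Sequences sampled per generator call.
#' @param attempt_cap Maximum sampled sequences before giving up (default
#'   `1000 * n_candidates`); a partial set is returned with a warning.
#' @param temperature,top_k Sampling controls passed to
#'   [sample_molecules()].
#' @param mi_threshold Mutual-information threshold for descriptor pruning.
#' @return A `candidate_set` object.
#' @export
reengineer <- function(input_smiles, constraints, generator, predictors,
                       n_candidates = 100L, seed = 1L, batch_size = 32L,
                       attempt_cap = NULL, temperature = 1.0, top_k = NULL,
                       mi_threshold = 0.9) {
  stopifnot(inherits(generator, "herg_transformer"),
            length(constraints) >= 1L)
  if (!smiles_valid(input_smiles)) stop("unparseable input: ", input_smiles)
  for (ct in constraints) {
    if (!ct$channel %in% names(predictors)) {
      stop("no predictor supplied for channel ", ct$channel)
    }
  }
  if (is.null(attempt_cap)) attempt_cap <- 1000L * max(n_candidates, 1L)
  rng <- rng_make(seed)
  input_can <- canonicalize_smiles(input_smiles)
  scaffold <- murcko_scaffold(input_smiles)
  props <- as.numeric(physchem_properties(input_smiles)[1L, ])
  accepted <- character(0)
  acc_preds <- list()
  n_sampled <- 0L
  n_valid <- 0L
  n_screened <- 0L
  seen <- character(0)
  while (length(accepted) < n_candidates && n_sampled < attempt_cap) {
    draw <- sample_molecules(generator, scaffold, props, n = batch_size,
                             temperature = temperature, top_k = top_k,
                             rng = rng)
    n_sampled <- n_sampled + batch_size
    if (length(draw$smiles) == 0L) next
    n_valid <- n_valid + length(draw$smiles)
    cans <- canonicalize_smiles(draw$smiles)
    # a canonical form can exceed the featurizer block even when the raw
    # sampled string did not; such candidates cannot be scored
    usable <- rep(TRUE, length(cans))
    for (m in predictors) {
      if (m$config$use_transformer) {
        usable <- usable & can_encode(m$featurizer, cans)
      }
    }
    cans <- cans[usable]
    if (length(cans) == 0L) next
    fresh <- !(cans %in% c(seen, input_can)) & !duplicated(cans)
    seen <- c(seen, cans[fresh])
    batch <- unique(cans[fresh])
    if (length(batch) == 0L) next
    preds <- lapply(predictors, function(m) predict(m, batch))
    for (i in seq_along(batch)) {
      if (length(accepted) >= n_candidates) break
      n_screened <- n_screened + 1L
      row <- lapply(preds, `[[`, i)
      if (apply_constraints(row, constraints)) {
        accepted <- c(accepted, batch[i])
        acc_preds[[length(acc_preds) + 1L]] <- unlist(row)
      }
    }
  }
  if (length(accepted) < n_candidates) {
    warning("attempt cap reached: returning ", length(accepted), " of ",
            n_candidates, " requested candidates")
  }
  stats_out <- list(n_sampled = n_sampled,
                    validity_rate = if (n_sampled) n_valid / n_sampled else 0,
                    filter_pass_rate =
                      if (n_screened) length(accepted) / n_screened else 0)
  pred_df <- if (length(acc_preds)) {
    as.data.frame(do.call(rbind, acc_preds))
  } else {
    as.data.frame(matrix(numeric(0), 0L, length(predictors),
                         dimnames = list(NULL, names(predictors))))
  }
  names(pred_df) <- paste0("pred_", names(predictors))
  if (length(accepted) == 0L) {
    return(structure(list(
      input = input_can, scaffold = scaffold,
      candidates = cbind(data.frame(rank = integer(0),
                                    smiles = character(0),
                                    similarity = numeric(0)), pred_df),
      keep_mask = NULL, stats = stats_out, seed = seed),
      class = "candidate_set"))
  }
  # descriptor block over input + candidates, z-scored, pruned, ranked
  dm <- descriptor_matrix(c(input_can, accepted))
  mu <- colMeans(dm)
  sdv <- apply(dm, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(dm, 2L, mu), 2L, sdv, "/")
  keep_mask <- if (nrow(dm) >= 3L) {
    suppressWarnings(prune_redundant(z, mi_threshold))
  } else rep(TRUE, ncol(dm))
  zk <- z[, keep_mask, drop = FALSE]
  ranking <- rank_candidates(zk[1L, ], zk[-1L, , drop = FALSE], accepted)
  ord <- match(ranking$smiles, accepted)
  out <- cbind(ranking, pred_df[ord, , drop = FALSE])
  rownames(out) <- NULL
  structure(list(input = input_can, scaffold = scaffold, candidates = out,
                 keep_mask = keep_mask, stats = stats_out, seed = seed),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Re-engineered candidate set for input:", x$input, "\n")
  cat("  scaffold:", if (nzchar(x$scaffold)) x$scaffold else "(acyclic)",
      "\n")
  cat("  candidates:", nrow(x$candidates),
      sprintf("(sampled %d, validity %.2f, filter pass %.2f)\n",
              x$stats$n_sampled, x$stats$validity_rate,
              x$stats$filter_pass_rate))
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates, 5))
    if (nrow(x$candidates) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Plot a candidate set in PCA chemical space
#'
#' @param x A `candidate_set`.
#' @param background_smiles Background corpus sample for context.
#' @param ... Passed to [plot()].
#' @method plot candidate_set
#' @export
plot.candidate_set <- function(x, background_smiles = character(0), ...) {
  proj <- chem_space_projection(x$input, x$candidates$smiles,
                                background_smiles)
  co <- proj$coords
  cols <- c(input = "#E6AB02", candidate = "#7570B3",
            background = "#D95F02")
  graphics::plot(co$PC1, co$PC2, col = cols[co$group],
                 pch = ifelse(co$group == "input", 17, 19),
                 cex = ifelse(co$group == "input", 1.8, 0.8),
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * proj$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * proj$explained_variance[2]), ...)
  graphics::legend("topright", legend = names(cols), col = cols,
                   pch = c(17, 19, 19), bty = "n")
  invisible(proj)
}
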