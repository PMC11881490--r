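# SMILES tokenization and corpus preprocessing for the transformer models.

# Token classes, longest-match first: bracket atoms, %nn ring closures,
# two-letter halogens, then every single-character SMILES symbol.
.SMI_TOKEN_RE <- paste0(
  "(\\[[^\\]]+\\])",      # bracket atom, e.g. [nH], [N+], [C@@H]
  "|(%[0-9]{2})",         # two-digit ring-bond label
  "|(Cl|Br)",             # two-letter organic-subset atoms
  "|([BCNOPSFIbcnosp])",  # one-letter organic-subset atoms
  "|([0-9])",             # ring-bond digit
  "|([-=#$:/\\\\().*])"   # bonds, branches, disconnection, wildcard
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the token alphabet used by the transformer
#' models: bracket atoms (`[nH]`, `[N+]`, `[C@@H]`, ...), two-digit `%nn`
#' ring-bond labels and the two-letter elements `Cl`/`Br` are single tokens;
#' everything else tokenizes per character. Concatenating the returned tokens
#' always reproduces the input exactly.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens.
#' @examples
#' smi_tokenize("CCO")
#' smi_tokenize("CC(=O)N[C@@H](Cl)Br")
#' @export
smi_tokenize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("'smiles' must be a single non-empty string")
  }
  m <- gregexpr(.SMI_TOKEN_RE, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    stop(sprintf("unrecognized SMILES character '%s' at offset 1",
                 substr(smiles, 1, 1)))
  }
  ends <- m + attr(m, "match.length") - 1L
  # Tokens must tile the string; the first gap is the offending character.
  expected <- c(1L, ends[-length(ends)] + 1L)
  bad <- which(m != expected)
  if (length(bad) > 0L || ends[length(ends)] != nchar(smiles)) {
    off <- if (length(bad) > 0L) expected[bad[1]] else ends[length(ends)] + 1L
    stop(sprintf("unrecognized SMILES character '%s' at offset %d",
                 substr(smiles, off, off), off))
  }
  substring(smiles, m, ends)
}

#' Reassemble tokens into a SMILES string
#'
#' Inverse of [smi_tokenize()]: plain concatenation.
#'
#' @param tokens Character vector of tokens.
#' @return A single SMILES string.
#' @export
smi_detokenize <- function(tokens) paste0(tokens, collapse = "")

.SPECIAL_TOKENS <- c(pad = "<pad>", cls = "[CLS]", eos = "[EOS]",
                     mask = "<MASK>")

#' Build a token vocabulary from a SMILES corpus
#'
#' Counts token occurrences over the corpus and keeps every token that occurs
#' at least `min_count` times, mirroring the corpus-curation rule of dropping
#' rare-token molecules. Four special tokens (`<pad>`, `[CLS]`, `[EOS]`,
#' `<MASK>`) are reserved at ids 0--3 and can never be produced by tokenizing
#' a molecule.
#'
#' @param corpus Character vector of SMILES strings.
#' @param min_count Minimum number of occurrences for a token to be kept.
#' @return An object of class `smiles_vocab` with elements `token_to_id`
#'   (named integer vector, ids contiguous from 0), `specials`, `min_count`
#'   and `dropped` (tokens seen but below the cutoff).
#' @export
build_vocabulary <- function(corpus, min_count = 1L) {
  if (length(corpus) == 0L) stop("'corpus' must be non-empty")
  counts <- table(unlist(lapply(corpus, smi_tokenize)))
  keep <- names(counts)[counts >= min_count]
  dropped <- setdiff(names(counts), keep)
  if (length(keep) == 0L) {
    stop("no token survives min_count = ", min_count,
         "; lower the cutoff or enlarge the corpus")
  }
  keep <- sort(keep)
  tokens <- c(unname(.SPECIAL_TOKENS), keep)
  ids <- seq_along(tokens) - 1L
  names(ids) <- tokens
  structure(
    list(token_to_id = ids, specials = as.list(.SPECIAL_TOKENS),
         min_count = as.integer(min_count), dropped = dropped),
    class = "smiles_vocab"
  )
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$token_to_id), "tokens (4 special),",
      "min_count =", x$min_count, "\n")
  if (length(x$dropped)) {
    cat("dropped below cutoff:", paste(x$dropped, collapse = " "), "\n")
  }
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$token_to_id)

special_ids <- function(vocab) {
  vapply(vocab$specials, function(t) unname(vocab$token_to_id[[t]]),
         integer(1))
}

# Encode one token vector; NA for out-of-vocabulary tokens.
encode_tokens <- function(tokens, vocab) {
  unname(vocab$token_to_id[tokens])
}

#' Preprocess a SMILES corpus into fixed-length token sequences
#'
#' Drops molecules that contain out-of-vocabulary tokens or more than
#' `max_content_len` tokens, then lays every survivor out as
#' `[CLS], tokens..., [EOS], <pad>...` with exactly `max_content_len` content
#' slots, giving a constant total block length of `max_content_len + 2`.
#'
#' @param corpus Character vector of SMILES strings.
#' @param vocab A `smiles_vocab`.
#' @param max_content_len Maximum (and padded-to) number of content tokens
#'   per molecule; the default 133 covers 99.99\% of drug-like corpora.
#' @return An object of class `token_corpus`: a list with `ids` (integer
#'   matrix, one row per molecule, `max_content_len + 2` columns),
#'   `content_len` (tokens per molecule), `smiles` (the surviving strings),
#'   `n_dropped` and `vocab`.
#' @export
preprocess_corpus <- function(corpus, vocab, max_content_len = 133L) {
  stopifnot(inherits(vocab, "smiles_vocab"), max_content_len >= 1L)
  sp <- special_ids(vocab)
  block_len <- max_content_len + 2L
  rows <- vector("list", length(corpus))
  lens <- integer(length(corpus))
  ok <- logical(length(corpus))
  for (i in seq_along(corpus)) {
    toks <- tryCatch(smi_tokenize(corpus[[i]]), error = function(e) NULL)
    if (is.null(toks) || length(toks) > max_content_len) next
    ids <- encode_tokens(toks, vocab)
    if (anyNA(ids)) next
    ok[i] <- TRUE
    lens[i] <- length(ids)
    rows[[i]] <- c(sp[["cls"]], ids, sp[["eos"]],
                   rep(sp[["pad"]], max_content_len - length(ids)))
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " molecule(s) dropped (out-of-vocabulary or > ",
            max_content_len, " tokens)")
  }
  ids <- do.call(rbind, rows[ok])
  if (is.null(ids)) ids <- matrix(integer(0), 0L, block_len)
  structure(
    list(ids = ids, content_len = lens[ok], smiles = corpus[ok],
         n_dropped = n_dropped, max_content_len = as.integer(max_content_len),
         block_len = as.integer(block_len), vocab = vocab),
    class = "token_corpus"
  )
}

#' @export
print.token_corpus <- function(x, ...) {
  cat("Token corpus:", nrow(x$ids), "sequences, block length", x$block_len,
      "(", x$max_content_len, "content slots ),", x$n_dropped, "dropped\n")
  invisible(x)
}

#' Encode a single SMILES string with a fitted vocabulary
#'
#' @param smiles SMILES string; must tokenize entirely inside `vocab`.
#' @param vocab A `smiles_vocab`.
#' @param max_content_len Content slots (padded layout as in
#'   [preprocess_corpus()]).
#' @return Integer vector of length `max_content_len + 2`.
#' @export
encode_sequence <- function(smiles, vocab, max_content_len = 133L) {
  toks <- smi_tokenize(smiles)
  ids <- encode_tokens(toks, vocab)
  if (anyNA(ids)) {
    stop("out-of-vocabulary token(s): ",
         paste(unique(toks[is.na(ids)]), collapse = " "))
  }
  if (length(ids) > max_content_len) {
    stop("sequence has ", length(ids), " tokens; limit is ", max_content_len)
  }
  sp <- special_ids(vocab)
  c(sp[["cls"]], ids, sp[["eos"]],
    rep(sp[["pad"]], max_content_len - length(ids)))
}

#' Split a processed corpus into training and validation parts
#'
#' Random, disjoint and exhaustive split; the training share is
#' `round(n * train_frac)` items, matching a 95/5 split at the default.
#'
#' @param corpus A `token_corpus`.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train` and `validation`, both `token_corpus` objects.
#' @export
split_corpus <- function(corpus, train_frac = 0.95, seed = 1L) {
  stopifnot(inherits(corpus, "token_corpus"))
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("'train_frac' must lie strictly between 0 and 1")
  }
  n <- nrow(corpus$ids)
  if (n < 2L) stop("need at least 2 sequences to split")
  n_train <- max(1L, min(n - 1L, as.integer(round(n * train_frac))))
  rng <- rng_make(seed)
  idx <- rng_sample(rng, n, n)
  take <- function(i) {
    out <- corpus
    out$ids <- corpus$ids[i, , drop = FALSE]
    out$content_len <- corpus$content_len[i]
    out$smiles <- corpus$smiles[i]
    out
  }
  list(train = take(sort(idx[seq_len(n_train)])),
       validation = take(sort(idx[(n_train + 1L):n])))
}

#' Corrupt a token sequence for masked-token training
#'
#' Each content token (never `[CLS]`, `[EOS]` or padding) is independently
#' selected with probability `select_prob`; a selected token is replaced by
#' `<MASK>` with probability `mask_frac`, by a random non-special vocabulary
#' token with probability `random_frac`, and left unchanged otherwise. The
#' returned loss mask marks exactly the selected positions.
#'
#' @param ids Integer vector: one padded sequence (as from
#'   [encode_sequence()]) or a row of a `token_corpus`.
#' @param vocab The `smiles_vocab` the ids were encoded with.
#' @param select_prob Per-token selection probability (default 0.15).
#' @param mask_frac,random_frac,keep_frac Replacement split over selected
#'   tokens; must sum to 1 (defaults 0.8 / 0.1 / 0.1).
#' @param rng A random stream from [rng_make()].
#' @return List with `corrupted` (ids after corruption), `target` (the
#'   original ids) and `loss_mask` (logical, TRUE at selected positions).
#' @export
apply_masking <- function(ids, vocab, select_prob = 0.15, mask_frac = 0.8,
                          random_frac = 0.1, keep_frac = 0.1,
                          rng = rng_make(1L)) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  if (abs(mask_frac + random_frac + keep_frac - 1) > 1e-8) {
    stop("mask_frac + random_frac + keep_frac must equal 1")
  }
  sp <- special_ids(vocab)
  content <- !(ids %in% sp)
  sel <- content & (rng_runif(rng, length(ids)) < select_prob)
  corrupted <- ids
  if (any(sel)) {
    u <- rng_runif(rng, sum(sel))
    action <- ifelse(u < mask_frac, "mask",
                     ifelse(u < mask_frac + random_frac, "random", "keep"))
    pos <- which(sel)
    corrupted[pos[action == "mask"]] <- sp[["mask"]]
    n_rand <- sum(action == "random")
    if (n_rand > 0L) {
      pool <- setdiff(unname(vocab$token_to_id), sp)
      corrupted[pos[action == "random"]] <-
        pool[rng_sample(rng, length(pool), n_rand, replace = TRUE)]
    }
  }
  list(corrupted = corrupted, target = ids, loss_mask = sel)
}
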