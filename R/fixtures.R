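# Synthetic data generators: a fragment-grammar SMILES corpus (so the
# language models have something to train on without external downloads)
# and planted-activity labels whose pIC50 depends on lipophilicity,
# polarity and basic-nitrogen content plus Gaussian noise, mirroring the
# qualitative structure-activity correlations seen in public cardiac
# channel data (hERG activity rising with LogP, falling with TPSA).

.FIX_CORES <- list(
  list(plain = "c1ccccc1",   mono = "c1ccc(%s)cc1",
       di = "c1ccc(%s)c(%s)c1"),
  list(plain = "c1ccncc1",   mono = "c1cc(%s)ncc1",
       di = "c1cc(%s)nc(%s)c1"),
  list(plain = "c1ccsc1",    mono = "c1cc(%s)sc1", di = NULL),
  list(plain = "C1CCCCC1",   mono = "C1CCC(%s)CC1",
       di = "C1CC(%s)C(%s)CC1"),
  list(plain = "C1CCNCC1",   mono = "C1CCN(%s)CC1", di = NULL),
  list(plain = "C1CCOCC1",   mono = "C1CC(%s)OCC1", di = NULL),
  list(plain = "C1CCNC1",    mono = "C1CCN(%s)C1", di = NULL),
  list(plain = "C1COCCN1",   mono = "C1COCCN1%s",  di = NULL),
  list(plain = "c1ccc2ccccc2c1", mono = "c1ccc2cc(%s)ccc2c1", di = NULL)
)

.FIX_SUBS <- c("C", "CC", "CCC", "CCCC", "O", "OC", "OCC", "N", "NC",
               "N(C)C", "CN", "CCN(C)C", "F", "Cl", "Br", "C(=O)O",
               "C(=O)OC", "C(=O)N", "C#N", "C(F)(F)F", "S(=O)(=O)N",
               "CCO", "CO", "C(C)C")

.FIX_LINKERS <- c("", "C", "CC", "CCC", "OC", "C(=O)", "C(=O)N", "CN",
                  "OCC", "S")

# Shift ring-closure digits so nested ring fragments never collide.
.shift_ring_digits <- function(s, offset) {
  chartr("12", paste0(offset, offset + 1L), s)
}

.fix_one <- function(rng, max_heavy_atoms) {
  n_rings <- c(1L, 2L, 3L)[findInterval(rng_runif(rng, 1L),
                                        c(0, 0.30, 0.75, 1))]
  pick <- function(x) x[[rng_sample(rng, length(x), 1L)]]
  build_ring <- function(depth) {
    core <- pick(.FIX_CORES)
    # chain onto the next ring?
    tail_part <- if (depth < n_rings) {
      paste0(pick(.FIX_LINKERS),
             .shift_ring_digits(build_ring(depth + 1L), 2L * depth + 1L))
    } else if (rng_runif(rng, 1L) < 0.8) {
      pick(.FIX_SUBS)
    } else ""
    if (!nzchar(tail_part)) return(core$plain)
    use_di <- !is.null(core$di) && depth == 1L && rng_runif(rng, 1L) < 0.35
    if (use_di) sprintf(core$di, tail_part, pick(.FIX_SUBS))
    else sprintf(core$mono, tail_part)
  }
  build_ring(1L)
}

#' Generate a synthetic SMILES corpus from a fragment grammar
#'
#' Assembles drug-like molecules from ring cores (aromatic, heteroaromatic,
#' saturated), linkers and substituents. Every emitted string is valid by
#' construction of the grammar (and double-checked with the parser); the
#' corpus is deduplicated and reproducible from the seed alone.
#'
#' @param n Number of unique molecules.
#' @param seed Integer seed.
#' @param max_heavy_atoms Upper bound on heavy atoms per molecule.
#' @return Character vector of `n` unique valid SMILES strings.
#' @export
make_corpus <- function(n, seed = 1L, max_heavy_atoms = 40L) {
  stopifnot(n >= 1L)
  rng <- rng_make(seed)
  out <- character(0)
  attempts <- 0L
  max_attempts <- 200L * n
  while (length(out) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    s <- .fix_one(rng, max_heavy_atoms)
    if (s %in% out) next
    toks <- smi_tokenize(s)
    heavy <- sum(grepl("^[A-Za-z]|^\\[", toks) & !grepl("^[0-9%]", toks))
    if (heavy > max_heavy_atoms) next
    if (!smiles_valid(s)) next
    out <- c(out, s)
  }
  if (length(out) < n) {
    stop("fragment grammar exhausted after ", attempts, " attempts (",
         length(out), "/", n, " unique molecules); enlarge the grammar or ",
         "lower n")
  }
  out
}

# Does the molecule contain a basic (aliphatic, non-amide) nitrogen?
.has_basic_nitrogen <- function(mol) {
  a <- mol$atoms
  el <- a$element
  n <- mol$n_atoms
  bonds <- mol$bonds
  nbrs <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      nbrs[[bonds[k, 1]]] <- c(nbrs[[bonds[k, 1]]], k)
      nbrs[[bonds[k, 2]]] <- c(nbrs[[bonds[k, 2]]], k)
    }
  }
  other_end <- function(k, v) if (bonds[k, 1] == v) bonds[k, 2] else bonds[k, 1]
  has_double_O <- vapply(seq_len(n), function(v) {
    any(vapply(nbrs[[v]], function(k) {
      bonds[k, 3] == 2L && el[other_end(k, v)] == "O"
    }, logical(1)))
  }, logical(1))
  any(vapply(which(el == "N" & !a$aromatic), function(v) {
    all_single <- length(nbrs[[v]]) == 0L ||
      all(vapply(nbrs[[v]], function(k) bonds[k, 3] == 1L, logical(1)))
    no_amide <- !any(vapply(nbrs[[v]], function(k) {
      w <- other_end(k, v)
      el[w] == "C" && has_double_O[w]
    }, logical(1)))
    all_single && no_amide
  }, logical(1)))
}

#' Planted-activity labels for a synthetic corpus
#'
#' Assigns each molecule a pIC50 of
#' `intercept + b_logp * LogP - b_tpsa * TPSA/100 + b_basic_n * basicN +
#' Normal(0, noise_sd)`, where `basicN` indicates a basic aliphatic
#' nitrogen. The default coefficients give a positive pIC50-LogP and a
#' negative pIC50-TPSA correlation and a blocker rate (pIC50 >= 5) near
#' 50\% on the default grammar, which maximizes test power; real channel
#' datasets are more imbalanced.
#'
#' @param corpus Character vector of SMILES strings.
#' @param channel Channel tag carried through to the records.
#' @param intercept,b_logp,b_tpsa,b_basic_n Planted coefficients.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return Data.frame with columns `smiles`, `channel`, `pic50`, `blocker`,
#'   plus the generating features `logp`, `tpsa`, `basic_n`.
#' @export
make_labeled_set <- function(corpus, channel = "hERG", intercept = 3.6,
                             b_logp = 0.55, b_tpsa = 0.9, b_basic_n = 0.8,
                             noise_sd = 0.4, seed = 1L) {
  stopifnot(noise_sd > 0, length(corpus) >= 1L)
  rng <- rng_make(seed)
  props <- physchem_properties(corpus)
  mols <- parse_mols(corpus)
  basic_n <- vapply(mols, .has_basic_nitrogen, logical(1))
  mu <- intercept + b_logp * props$logp - b_tpsa * props$tpsa / 100 +
    b_basic_n * as.numeric(basic_n)
  pic50 <- mu + rng_rnorm(rng, length(corpus), sd = noise_sd)
  data.frame(smiles = corpus, channel = channel, pic50 = pic50,
             blocker = pic50 >= 5.0, logp = props$logp, tpsa = props$tpsa,
             basic_n = basic_n, stringsAsFactors = FALSE)
}
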