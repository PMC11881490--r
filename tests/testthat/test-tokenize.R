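test_that("tokenization keeps multi-character tokens atomic and round-trips", {
  expect_equal(smi_tokenize("CCO"), c("C", "C", "O"))
  expect_equal(smi_tokenize("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  toks <- smi_tokenize("CC(=O)N[C@@H](Cl)Br")
  expect_true(all(c("Cl", "Br", "[C@@H]") %in% toks))
  expect_equal(smi_detokenize(toks), "CC(=O)N[C@@H](Cl)Br")
  expect_equal(smi_tokenize("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
})

test_that("tokenization errors name the offending offset", {
  expect_error(smi_tokenize("CCxO"), "offset 3")
  expect_error(smi_tokenize(""), "non-empty")
})

test_that("round trip holds over a large fuzzed corpus", {
  corpus <- hf_big_corpus()
  ok <- vapply(corpus, function(s) {
    identical(smi_detokenize(smi_tokenize(s)), s)
  }, logical(1))
  expect_true(all(ok))
})

test_that("vocabulary keeps exactly the tokens above the count cutoff", {
  v2 <- build_vocabulary(c("CC", "CC", "CO"), min_count = 2)
  non_special <- setdiff(names(v2$token_to_id), unlist(v2$specials))
  expect_setequal(non_special, "C")
  expect_true("O" %in% v2$dropped)

  v1 <- build_vocabulary(c("CC", "CC", "CO"), min_count = 1)
  expect_setequal(setdiff(names(v1$token_to_id), unlist(v1$specials)),
                  c("C", "O"))

  # ids contiguous from 0, specials distinct and reserved
  ids <- sort(unname(v1$token_to_id))
  expect_equal(ids, seq_along(ids) - 1L)
  expect_equal(length(unique(unlist(v1$specials))), 4L)
  expect_error(build_vocabulary(c("CC"), min_count = 10), "no token")
})

test_that("vocabulary counting matches a brute-force tally on a synthetic corpus", {
  corpus <- hf_corpus()[1:200]
  v <- build_vocabulary(corpus, min_count = 5)
  counts <- table(unlist(lapply(corpus, smi_tokenize)))
  expected <- sort(names(counts)[counts >= 5])
  expect_equal(sort(setdiff(names(v$token_to_id), unlist(v$specials))),
               expected)
})

test_that("preprocessing pads to a constant block and drops long or OOV strings", {
  v <- build_vocabulary(c("CCO", "CCN"))
  tc <- suppressMessages(preprocess_corpus(c("CCO", "CCNCC", "CCCl"), v,
                                           max_content_len = 133L))
  # Cl is out of vocabulary -> dropped
  expect_equal(nrow(tc$ids), 2L)
  expect_equal(tc$n_dropped, 1L)
  expect_equal(ncol(tc$ids), 135L)
  sp <- unname(v$token_to_id[unlist(v$specials)])
  pad <- unname(v$token_to_id[[v$specials$pad]])
  expect_equal(sum(tc$ids[1, ] == pad), 130L)  # 133 slots - 3 tokens

  long <- paste(rep("C", 134), collapse = "")
  tc2 <- suppressMessages(preprocess_corpus(c(long, "CCO"), v,
                                            max_content_len = 133L))
  expect_equal(nrow(tc2$ids), 1L)
  boundary <- paste(rep("C", 133), collapse = "")
  tc3 <- preprocess_corpus(c(boundary), v, max_content_len = 133L)
  expect_equal(nrow(tc3$ids), 1L)
})

test_that("preprocessing survivor count matches a brute-force filter", {
  corpus <- hf_corpus()[1:100]
  v <- hf_vocab()
  tc <- suppressMessages(preprocess_corpus(corpus, v, max_content_len = 30L))
  manual <- vapply(corpus, function(s) {
    toks <- smi_tokenize(s)
    length(toks) <= 30L && !anyNA(encode_tokens(toks, v))
  }, logical(1))
  expect_equal(nrow(tc$ids), sum(manual))
  expect_true(all(apply(tc$ids, 1, length) == 32L))
})

test_that("corpus splitting is disjoint, exhaustive and reproducible", {
  tc <- hf_tcorpus()
  sp <- split_corpus(tc, 0.95, seed = 42)
  n <- nrow(tc$ids)
  expect_equal(nrow(sp$train$ids) + nrow(sp$validation$ids), n)
  expect_equal(nrow(sp$train$ids), round(0.95 * n))
  expect_length(intersect(sp$train$smiles, sp$validation$smiles), 0)
  sp2 <- split_corpus(tc, 0.95, seed = 42)
  expect_identical(sp$train$smiles, sp2$train$smiles)
  sp3 <- split_corpus(tc, 0.95, seed = 43)
  expect_false(identical(sp$train$smiles, sp3$train$smiles))
  expect_error(split_corpus(tc, 1.2), "between 0 and 1")

  v <- build_vocabulary(c("CC", "CO"))
  two <- preprocess_corpus(c("CC", "CO"), v, max_content_len = 5L)
  sp4 <- split_corpus(two, 0.5, seed = 1)
  expect_equal(nrow(sp4$train$ids), 1L)
  expect_equal(nrow(sp4$validation$ids), 1L)
})

test_that("masking respects the selection scheme and never touches specials", {
  v <- hf_vocab()
  smi <- hf_corpus()[[1]]
  ids <- encode_sequence(smi, v, max_content_len = 36L)
  sp <- unname(v$token_to_id[unlist(v$specials)])

  # degenerate settings
  m0 <- apply_masking(ids, v, select_prob = 0, rng = rng_make(1))
  expect_identical(m0$corrupted, ids)
  expect_false(any(m0$loss_mask))

  m1 <- apply_masking(ids, v, select_prob = 1, mask_frac = 1,
                      random_frac = 0, keep_frac = 0, rng = rng_make(1))
  content <- !(ids %in% sp)
  mask_id <- unname(v$token_to_id[[v$specials$mask]])
  expect_true(all(m1$corrupted[content] == mask_id))
  expect_identical(m1$corrupted[!content], ids[!content])
  expect_true(all(m1$loss_mask == content))

  expect_error(apply_masking(ids, v, mask_frac = 0.5, random_frac = 0.1,
                             keep_frac = 0.1), "must equal 1")

  # specials never altered over many random plans
  rng <- rng_make(7)
  for (k in 1:500) {
    m <- apply_masking(ids, v, rng = rng)
    expect_identical(m$corrupted[!content], ids[!content])
    expect_false(any(m$loss_mask[!content]))
    expect_identical(m$target, ids)
  }
})
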