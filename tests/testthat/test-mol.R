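# Canonicalization, validity, scaffolds, properties, fingerprints, graphs.
# Reference scaffold strings were computed with an independent Murcko
# implementation (RDKit) and are asserted up to canonicalization.

test_that("canonicalization maps spellings of one molecule to one string", {
  expect_equal(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_equal(canonicalize_smiles("C1=CC=CC=C1"),
               canonicalize_smiles("c1ccccc1"))
  s <- canonicalize_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(canonicalize_smiles(s), s)  # idempotent
  expect_error(canonicalize_smiles("C(("), "cannot parse")
})

test_that("validity screening rejects malformed strings", {
  expect_true(all(smiles_valid(c("CCO", "c1ccccc1", "C[N+](C)(C)C"))))
  expect_false(any(hf_quiet(
    smiles_valid(c("", "C1CC", "CC)", "((", "[Xx]", "1cc", "=O=")))))
})

test_that("Murcko scaffolds keep rings and linkers and drop side chains", {
  expect_equal(murcko_scaffold("CCCC"), "")
  expect_equal(murcko_scaffold("c1ccccc1"), canonicalize_smiles("c1ccccc1"))
  expect_equal(murcko_scaffold("CCc1ccccc1"),
               canonicalize_smiles("c1ccccc1"))
  # reference Murcko results (independent implementation), canonicalized
  expect_equal(murcko_scaffold("c1ccccc1C(=O)NC1CCNCC1"),
               canonicalize_smiles("O=C(NC1CCNCC1)c1ccccc1"))
  expect_equal(murcko_scaffold("CC(=O)c1ccccc1"),
               canonicalize_smiles("c1ccccc1"))
  expect_equal(murcko_scaffold("C1CCN(CC1)Cc1ccc2ccccc2c1"),
               canonicalize_smiles("c1ccc2cc(CN3CCCCC3)ccc2c1"))
  expect_equal(murcko_scaffold("O=C1CCCCC1"),
               canonicalize_smiles("O=C1CCCCC1"))
})

test_that("scaffold extraction is idempotent over a fuzzed corpus", {
  smis <- hf_corpus()[seq(1, 300, by = 6)]
  sc <- murcko_scaffold(smis)
  sc <- sc[nzchar(sc)]
  expect_equal(murcko_scaffold(sc), sc)
})

test_that("the ten physicochemical properties are computed in fixed order", {
  expect_equal(PHYSCHEM_NAMES,
               c("mw", "n_rings", "n_rotatable_bonds", "n_hbd", "n_hba",
                 "tpsa", "n_heteroatoms", "logp", "n_stereocenters",
                 "formal_charge"))
  p <- hf_quiet(physchem_properties(c("C", "c1ccccc1", "C[N+](C)(C)C",
                                      "C/C=C/[C@@H](C)Cl")))
  expect_equal(names(p), PHYSCHEM_NAMES)
  expect_equal(p$n_rings, c(0, 1, 0, 0))
  expect_equal(p$formal_charge, c(0, 0, 1, 0))
  expect_equal(p$n_heteroatoms, c(0, 0, 1, 1))
  expect_equal(p$n_stereocenters, c(0, 0, 0, 1))
  expect_equal(p$n_rotatable_bonds[2], 0)
})

test_that("aspirin properties agree with direct toolkit computation", {
  p <- physchem_properties("CC(=O)Oc1ccccc1C(=O)O")
  ref <- ChemmineOB::forEachMol("SMILES", "CC(=O)Oc1ccccc1C(=O)O\n",
                                function(m) ChemmineOB::prop_OB(m))[[1]]
  expect_equal(p$mw, ref$MW, tolerance = 1e-3)
  expect_equal(p$tpsa, ref$TPSA, tolerance = 1e-3)
  expect_equal(p$logp, ref$logP, tolerance = 1e-3)
  expect_equal(p$n_hbd, ref$HBD)
  expect_equal(p$n_rings, 1)
})

test_that("ECFP4 fingerprints are 1024-bit, deterministic and discriminating", {
  fp <- ecfp4(c("CCO", "CCN", "CCO"))
  expect_equal(ncol(fp), 1024L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp[1, ], fp[3, ])
  tanimoto <- sum(fp[1, ] & fp[2, ]) / sum(fp[1, ] | fp[2, ])
  expect_lt(tanimoto, 1)
})

test_that("molecular graphs carry the documented 14 atom features", {
  g <- build_graph("CCO")
  expect_s3_class(g, "mol_graph")
  expect_equal(dim(g$node_features), c(3L, 14L))
  expect_equal(nrow(g$edges), 2L)
  o_row <- which(g$node_features[, "is_O"] == 1)
  expect_equal(unname(g$node_features[o_row, "hba"]), 1)
  expect_equal(unname(g$node_features[o_row, "hbd"]), 1)
  # terminal carbon: hydrophobic, one heavy neighbor
  expect_equal(unname(g$node_features[1, "hydrophobic"]), 1)
  expect_equal(unname(g$node_features[1, "n_heavy_neighbors"]), 1)
  expect_equal(unname(g$node_features[2, "n_hetero_neighbors"]), 1)

  gb <- build_graph("c1ccccc1")
  expect_equal(nrow(gb$node_features), 6L)
  expect_equal(nrow(gb$edges), 6L)
  expect_true(all(gb$node_features[, "aromatic"] == 1))
  expect_true(all(gb$node_features[, "in_ring"] == 1))
})

test_that("graph features of the worked featurization molecule check out", {
  g <- build_graph("CCC(=O)CCNC(C)C(=O)c1ccncc1C")
  f <- g$node_features
  # atom 1: terminal methyl carbon
  expect_equal(unname(f[1, c("is_C", "hydrophobic", "n_heavy_neighbors",
                             "n_hetero_neighbors", "aromatic")]),
               c(1, 1, 1, 0, 0))
  expect_equal(unname(f[1, "mass"]), 12.011)
  # atom 4: carbonyl oxygen — acceptor, no H, one heavy neighbor
  expect_equal(unname(f[4, c("is_O", "hba", "hbd", "n_heavy_neighbors",
                             "in_ring")]), c(1, 1, 0, 1, 0))
  # ring nitrogen: aromatic, in ring, acceptor without H
  n_ring <- which(f[, "is_N"] == 1 & f[, "aromatic"] == 1)
  expect_length(n_ring, 1L)
  expect_equal(unname(f[n_ring, c("hba", "hbd", "in_ring")]), c(1, 0, 1))
  # amide-like chain N-H: donor
  n_chain <- which(f[, "is_N"] == 1 & f[, "aromatic"] == 0)
  expect_equal(unname(f[n_chain, "hbd"]), 1)
})

test_that("graph node count equals the parser's heavy-atom count (fuzz)", {
  smis <- hf_big_corpus()[seq(1, 1000, by = 5)]
  for (s in smis) {
    g <- build_graph(s)
    toks <- smi_tokenize(s)
    heavy <- sum(grepl("^\\[|^Cl$|^Br$|^[BCNOPSFIbcnosp]$", toks))
    expect_equal(nrow(g$node_features), heavy)
  }
})

test_that("cosine similarity follows the exact formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)), 0.9746,
               tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "equal length")
})
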