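# Molecular parsing and featurization on top of ChemmineR / ChemmineOB
# (OpenBabel). Everything downstream (properties, fingerprints, graphs,
# descriptors, scaffolds) works off the internal mol object built here.

.MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

.ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904,
                  I = 126.904, Si = 28.085, Se = 78.971)

.DEFAULT_VALENCE <- c(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, P = 3L,
                      S = 2L, Cl = 1L, Br = 1L, I = 1L, Si = 4L, Se = 2L)

# Non-strict rotatable-bond SMARTS (single, acyclic, both ends non-terminal,
# neither end triple-bonded).
.ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

.ob_convert <- function(from, to, source) {
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, source))
  out
}

#' Check SMILES validity
#'
#' A string is considered a valid molecule when it tokenizes under the SMILES
#' alphabet, its parentheses and ring-bond labels are balanced, and OpenBabel
#' parses it into a non-empty molecule. This is the filter applied to
#' generated strings before any property or activity computation.
#'
#' @param smiles Character vector of candidate SMILES strings.
#' @return Logical vector.
#' @export
.smi_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  toks <- tryCatch(smi_tokenize(s), error = function(e) NULL)
  if (is.null(toks)) return(FALSE)
  if (!any(grepl("[A-Za-z]", toks))) return(FALSE)  # no atoms at all
  depth <- 0L
  for (t in toks) {
    if (t == "(") depth <- depth + 1L
    if (t == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
  }
  if (depth != 0L) return(FALSE)
  # ring-bond labels must pair up
  ringlab <- toks[grepl("^[0-9]$|^%[0-9]{2}$", toks)]
  if (length(ringlab) && any(table(ringlab) %% 2L != 0L)) return(FALSE)
  TRUE
}

smiles_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (!.smi_syntax_ok(s)) return(FALSE)
    can <- tryCatch(.ob_convert("SMI", "CAN", paste0(s, "\n")),
                    error = function(e) "")
    nzchar(trimws(can))
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Maps every SMILES spelling of a molecule to one canonical string
#' (OpenBabel canonical SMILES). Idempotent.
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    can <- if (!.smi_syntax_ok(smiles[[i]])) "" else {
      tryCatch(.ob_convert("SMI", "CAN", paste0(smiles[[i]], "\n")),
               error = function(e) "")
    }
    can <- sub("[\t\n].*$", "", can)
    can <- trimws(can)
    if (!nzchar(can)) {
      stop("cannot parse SMILES: ", smiles[[i]])
    }
    out[[i]] <- can
  }
  out
}

# Parse a batch of SMILES into internal mol objects. Combines the kekulized
# SDF view (formal charges, integer bond orders) with the MOL2 view
# (Gasteiger partial charges, aromaticity flags).
parse_mols <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  bad <- !smiles_valid(smiles)
  if (any(bad)) {
    stop("invalid SMILES: ", paste(smiles[bad], collapse = ", "))
  }
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  sdf_txt <- .ob_convert("SMI", "SDF", src)
  sdfs <- .parse_v2000(sdf_txt)
  mol2 <- suppressWarnings(ChemmineOB::convertFormat(
    "SMI", "MOL2", src,
    options = data.frame(names = "partialcharge", args = "gasteiger")))
  m2 <- .parse_mol2(mol2)
  if (length(m2) != length(smiles) || length(sdfs) != length(smiles)) {
    stop("format conversion returned a different number of molecules (",
         length(sdfs), " SDF / ", length(m2), " MOL2) for ",
         length(smiles), " inputs")
  }
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    element <- sdfs[[i]]$element
    n <- length(element)
    fcharge <- sdfs[[i]]$formal_charge
    bonds <- sdfs[[i]]$bonds
    colnames(bonds) <- c("i", "j", "order")
    g2 <- m2[[i]]
    if (nrow(g2$atoms) != n ||
        !all(g2$atoms$element == element)) {
      stop("SDF/MOL2 atom-order mismatch for molecule ", smiles[[i]])
    }
    deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
    bondsum <- numeric(n)
    if (nrow(bonds)) {
      for (k in seq_len(nrow(bonds))) {
        bondsum[bonds[k, 1]] <- bondsum[bonds[k, 1]] + bonds[k, 3]
        bondsum[bonds[k, 2]] <- bondsum[bonds[k, 2]] + bonds[k, 3]
      }
    }
    dv <- unname(.DEFAULT_VALENCE[element])
    dv[is.na(dv)] <- bondsum[is.na(dv)]
    dv_eff <- ifelse(element == "C", dv - abs(fcharge), dv + fcharge)
    # hypervalent S/P: no implicit H once the drawn valence exceeds default
    nH <- pmax(0, dv_eff - bondsum)
    ring_bond <- .ring_bonds(n, bonds)
    in_ring <- rep(FALSE, n)
    if (any(ring_bond)) {
      in_ring[unique(c(bonds[ring_bond, 1], bonds[ring_bond, 2]))] <- TRUE
    }
    out[[i]] <- list(
      smiles = unname(smiles[[i]]),
      atoms = data.frame(
        element = element,
        formal_charge = fcharge,
        partial_charge = g2$atoms$charge,
        aromatic = g2$atoms$aromatic,
        in_ring = in_ring,
        degree = deg,
        n_implicit_h = as.integer(round(nH)),
        mass = unname(ifelse(is.na(.ATOMIC_MASS[element]), 0,
                             .ATOMIC_MASS[element])),
        stringsAsFactors = FALSE
      ),
      bonds = bonds,
      ring_bond = ring_bond,
      n_atoms = n
    )
  }
  names(out) <- NULL
  out
}

# Parse multi-record V2000 SDF text into element / formal-charge / bond
# tables (fixed-width fields; M CHG lines override atom-line charge codes).
.parse_v2000 <- function(text) {
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  lapply(recs, function(rec) {
    lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
    counts <- lines[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    atom_lines <- lines[5:(4 + na)]
    element <- trimws(substr(atom_lines, 32, 34))
    code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
    code[is.na(code)] <- 0L
    fcharge <- unname(.MDL_CHARGE[as.character(code)])
    fcharge[is.na(fcharge)] <- 0L
    if (nb > 0L) {
      bond_lines <- lines[(5 + na):(4 + na + nb)]
      bonds <- cbind(as.integer(substr(bond_lines, 1, 3)),
                     as.integer(substr(bond_lines, 4, 6)),
                     as.integer(substr(bond_lines, 7, 9)))
    } else {
      bonds <- matrix(integer(0), 0L, 3L)
    }
    for (chg in grep("^M  CHG", lines, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg)),
                               "[[:space:]]+")[[1]])
      k <- f[1]
      for (p in seq_len(k)) {
        fcharge[f[2 * p]] <- f[2 * p + 1]
      }
    }
    list(element = element, formal_charge = fcharge, bonds = bonds)
  })
}

# Parse multi-molecule MOL2 text into per-molecule atom tables.
.parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  out <- vector("list", length(mol_starts))
  bounds <- c(mol_starts, length(lines) + 1L)
  for (k in seq_along(mol_starts)) {
    seg <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    a0 <- grep("^@<TRIPOS>ATOM", seg)[1]
    nxt <- grep("^@<TRIPOS>", seg)
    nxt <- nxt[nxt > a0]
    stop_at <- if (length(nxt)) nxt[1] else length(seg) + 1L
    atom_lines <- seg[(a0 + 1L):(stop_at - 1L)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    type <- vapply(fields, `[[`, character(1), 6L)
    charge <- vapply(fields, function(f) as.numeric(f[[length(f)]]),
                     numeric(1))
    element <- sub("\\..*$", "", type)
    out[[k]] <- list(atoms = data.frame(
      element = element,
      aromatic = grepl("\\.ar$", type),
      charge = charge,
      stringsAsFactors = FALSE
    ))
  }
  out
}

# Which bonds lie on a cycle (non-bridge edges). A bond is a ring bond iff
# its endpoints stay connected after removing it; molecules are small enough
# for the direct check.
.ring_bonds <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  out <- logical(m)
  for (k in seq_len(m)) {
    src <- bonds[k, 1]; dst <- bonds[k, 2]
    seen <- logical(n)
    seen[src] <- TRUE
    frontier <- src
    while (length(frontier) && !seen[dst]) {
      nxt <- integer(0)
      for (e in seq_len(m)) {
        if (e == k) next
        a <- bonds[e, 1]; b <- bonds[e, 2]
        if (seen[a] && !seen[b] && a %in% frontier) {
          seen[b] <- TRUE; nxt <- c(nxt, b)
        } else if (seen[b] && !seen[a] && b %in% frontier) {
          seen[a] <- TRUE; nxt <- c(nxt, a)
        }
      }
      frontier <- nxt
    }
    out[k] <- seen[dst]
  }
  out
}

#' Murcko scaffold of a molecule
#'
#' Returns the molecule's ring systems plus the linkers connecting them, with
#' side chains removed. Atoms attached to the retained skeleton by a double
#' or triple bond (e.g. an exocyclic carbonyl oxygen) are kept, matching the
#' usual Murcko decomposition. Acyclic molecules yield the empty string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical scaffold SMILES ("" when acyclic).
#' @export
murcko_scaffold <- function(smiles) {
  mols <- parse_mols(smiles)
  vapply(mols, .murcko_one, character(1))
}

.murcko_one <- function(mol) {
  n <- mol$n_atoms
  bonds <- mol$bonds
  if (!any(mol$ring_bond)) return("")
  in_ring <- mol$atoms$in_ring
  keep <- rep(TRUE, n)
  # iteratively prune terminal atoms that are not in a ring
  repeat {
    deg <- tabulate(c(bonds[keep[bonds[, 1]] & keep[bonds[, 2]], 1],
                      bonds[keep[bonds[, 1]] & keep[bonds[, 2]], 2]),
                    nbins = n)
    drop <- keep & !in_ring & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # re-attach atoms multiple-bonded to the skeleton
  repeat {
    add <- rep(FALSE, n)
    for (k in seq_len(nrow(bonds))) {
      if (bonds[k, 3] >= 2L) {
        i <- bonds[k, 1]; j <- bonds[k, 2]
        if (keep[i] && !keep[j]) add[j] <- TRUE
        if (keep[j] && !keep[i]) add[i] <- TRUE
      }
    }
    if (!any(add)) break
    keep[add] <- TRUE
  }
  .subgraph_smiles(mol, which(keep))
}

# Canonical SMILES of an induced atom subset, via a hand-written V2000
# molfile round-tripped through OpenBabel.
.subgraph_smiles <- function(mol, atom_idx) {
  idx_map <- integer(mol$n_atoms)
  idx_map[atom_idx] <- seq_along(atom_idx)
  bonds <- mol$bonds
  bsel <- bonds[, 1] %in% atom_idx & bonds[, 2] %in% atom_idx
  bsub <- bonds[bsel, , drop = FALSE]
  na <- length(atom_idx); nb <- nrow(bsub)
  hdr <- sprintf("subgraph\n  hergforge\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 na, nb)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, mol$atoms$element[atom_idx])
  bl <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                        idx_map[bsub[, 1]], idx_map[bsub[, 2]], bsub[, 3])
        else character(0)
  chg <- which(mol$atoms$formal_charge[atom_idx] != 0L)
  chg_lines <- if (length(chg)) {
    vapply(chg, function(a) sprintf("M  CHG  1 %3d %3d", a,
                                    mol$atoms$formal_charge[atom_idx][a]),
           character(1))
  } else character(0)
  molfile <- paste(c(hdr, atoms, bl, chg_lines, "M  END", ""),
                   collapse = "\n")
  can <- .ob_convert("MOL", "CAN", molfile)
  can <- trimws(sub("[\t\n].*$", "", can))
  if (!nzchar(can)) stop("scaffold extraction failed for ", mol$smiles)
  can
}

#' Ten physicochemical properties of a molecule
#'
#' Computes, in the fixed order used for generator conditioning:
#' molecular weight (g/mol), number of rings (circuit rank), number of
#' rotatable bonds, hydrogen-bond donors, hydrogen-bond acceptors, TPSA
#' (Angstrom^2), number of heteroatoms, logP, number of specified
#' stereocenters, and net formal charge.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data.frame with one row per molecule and the ten columns above.
#' @export
physchem_properties <- function(smiles) {
  mols <- parse_mols(smiles)
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  refs <- ChemmineOB::forEachMol("SMILES", src, function(m) m)
  pr <- do.call(rbind, lapply(refs, function(m) ChemmineOB::prop_OB(m)))
  rot <- ChemmineOB::smartsSearch_OB(refs, .ROTATABLE_SMARTS,
                                     uniqueMatches = TRUE)
  can <- canonicalize_smiles(smiles)
  n_stereo <- vapply(can, function(s) {
    toks <- smi_tokenize(s)
    sum(grepl("^\\[[^]]*@", toks))
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(
    mw = pr$MW,
    n_rings = vapply(mols, function(m) {
      nrow(m$bonds) - m$n_atoms + .n_components(m)
    }, numeric(1)),
    n_rotatable_bonds = as.numeric(unname(rot)),
    n_hbd = pr$HBD,
    n_hba = pr$HBA1,
    tpsa = pr$TPSA,
    n_heteroatoms = vapply(mols, function(m) {
      sum(!(m$atoms$element %in% c("C", "H")))
    }, numeric(1)),
    logp = pr$logP,
    n_stereocenters = n_stereo,
    formal_charge = vapply(mols, function(m) {
      sum(m$atoms$formal_charge)
    }, numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' @rdname physchem_properties
#' @format NULL
#' @export
PHYSCHEM_NAMES <- c("mw", "n_rings", "n_rotatable_bonds", "n_hbd", "n_hba",
                    "tpsa", "n_heteroatoms", "logp", "n_stereocenters",
                    "formal_charge")

.n_components <- function(mol) {
  n <- mol$n_atoms
  parent <- seq_len(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[k, 1]; b <- mol$bonds[k, 2]
      while (parent[a] != a) a <- parent[a]
      while (parent[b] != b) b <- parent[b]
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), function(x) {
    while (parent[x] != x) x <- parent[x]; x
  }, integer(1))
  length(unique(roots))
}

#' ECFP4 fingerprints
#'
#' Extended-connectivity fingerprints of diameter 4 bonds (Morgan radius 2),
#' folded to `n_bits` bits.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Folded length (default 1024).
#' @return Integer 0/1 matrix, one row per molecule, `n_bits` columns.
#' @export
ecfp4 <- function(smiles, n_bits = 1024L) {
  stopifnot(n_bits >= 1L)
  bad <- !smiles_valid(smiles)
  if (any(bad)) stop("invalid SMILES: ", paste(smiles[bad], collapse = ", "))
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  refs <- ChemmineOB::forEachMol("SMILES", src, function(m) m)
  raw <- ChemmineOB::fingerprint_OB(refs, "ECFP4")
  raw <- matrix(as.numeric(raw), nrow = length(smiles))
  folded <- matrix(0L, nrow(raw), n_bits)
  cols <- (seq_len(ncol(raw)) - 1L) %% n_bits + 1L
  for (b in seq_len(ncol(raw))) {
    folded[, cols[b]] <- pmax(folded[, cols[b]], raw[, b])
  }
  storage.mode(folded) <- "integer"
  rownames(folded) <- NULL
  folded
}

.GRAPH_FEATURE_NAMES <- c("is_C", "is_N", "is_O", "is_P", "is_S",
                          "hydrophobic", "aromatic", "hba", "hbd", "in_ring",
                          "n_heavy_neighbors", "n_hetero_neighbors",
                          "partial_charge", "mass")

#' Molecular graph with 14-dimensional atom features
#'
#' Builds the graph representation used by the activity predictors: one node
#' per heavy atom, one undirected edge per bond labeled with its order.
#' Node features, in order: carbon/nitrogen/oxygen/phosphorus/sulfur
#' indicators, hydrophobicity indicator (carbon with no heteroatom
#' neighbor), aromaticity, hydrogen-bond acceptor (N or O), hydrogen-bond
#' donor (N or O bearing at least one hydrogen), ring membership, number of
#' bonds to heavy atoms, number of bonds to heteroatoms, Gasteiger partial
#' charge, and atomic mass.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol_graph`: list with `node_features`
#'   (n x 14 matrix), `edges` (m x 2 integer matrix), `edge_orders`
#'   (length-m numeric) and `smiles`.
#' @export
build_graph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  mol <- parse_mols(smiles)[[1]]
  a <- mol$atoms
  n <- mol$n_atoms
  hetero <- !(a$element %in% c("C", "H"))
  n_het_nb <- numeric(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      if (hetero[j]) n_het_nb[i] <- n_het_nb[i] + 1
      if (hetero[i]) n_het_nb[j] <- n_het_nb[j] + 1
    }
  }
  if (any(!is.finite(a$partial_charge))) {
    stop("partial-charge computation failed for ", smiles)
  }
  feats <- cbind(
    is_C = as.numeric(a$element == "C"),
    is_N = as.numeric(a$element == "N"),
    is_O = as.numeric(a$element == "O"),
    is_P = as.numeric(a$element == "P"),
    is_S = as.numeric(a$element == "S"),
    hydrophobic = as.numeric(a$element == "C" & n_het_nb == 0),
    aromatic = as.numeric(a$aromatic),
    hba = as.numeric(a$element %in% c("N", "O")),
    hbd = as.numeric(a$element %in% c("N", "O") & a$n_implicit_h > 0),
    in_ring = as.numeric(a$in_ring),
    n_heavy_neighbors = a$degree,
    n_hetero_neighbors = n_het_nb,
    partial_charge = a$partial_charge,
    mass = a$mass
  )
  structure(
    list(node_features = feats,
         edges = mol$bonds[, 1:2, drop = FALSE],
         edge_orders = as.numeric(mol$bonds[, 3]),
         smiles = mol$smiles),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("Molecular graph:", nrow(x$node_features), "atoms,",
      nrow(x$edges), "bonds (", x$smiles, ")\n")
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return Cosine of the angle between `a` and `b`, in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}
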