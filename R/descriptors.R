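# 2D chemical descriptor vectors, redundancy pruning, and the similarity
# machinery used to rank re-engineered candidates against the input molecule.
#
# The descriptor list is pinned: the shipped config file
# inst/extdata/descriptor_names.json freezes the 209 names and their order,
# and descriptor_matrix() asserts against it, so descriptor vectors stay
# comparable across sessions and toolkit versions.

.ELECTRONEG <- c(H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
                 P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66,
                 Si = 1.90, Se = 2.55)
.VALENCE_E <- c(B = 3, C = 4, N = 5, O = 6, F = 7, P = 5, S = 6, Cl = 7,
                Br = 7, I = 7, Si = 4, Se = 6)

.AC_PROPS <- c("mass", "charge", "eneg", "degree")
.AC_LAGS <- 1:8

#' Names of the pinned 2D descriptor set
#'
#' @return Character vector of the 209 descriptor names, in matrix column
#'   order.
#' @export
descriptor_names <- function() {
  c(PHYSCHEM_NAMES,
    "molar_refractivity", "heavy_atom_count",
    paste0("count_", c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                       "other")),
    "n_bonds", "n_single_bonds", "n_double_bonds", "n_triple_bonds",
    "n_aromatic_bonds", "n_ring_bonds", "n_ring_atoms", "frac_ring_atoms",
    "n_aromatic_atoms", "frac_aromatic_atoms", "n_deg1_atoms",
    "n_deg2_atoms", "n_deg3_atoms", "n_deg4_atoms", "mean_degree",
    "n_halogen", "frac_heteroatoms",
    "n_carbonyl", "n_hydroxyl", "n_ether", "n_nitrile", "n_primary_amine",
    "n_basic_nitrogen", "n_amide", "n_sulfonyl", "n_aromatic_nitrogen",
    "zagreb_m1", "zagreb_m2", "wiener_index", "balaban_j", "chi0", "chi1",
    "chi0v", "chi1v", "kappa1", "kappa2", "kappa3", "graph_diameter",
    "graph_radius", "mean_topological_distance", "platt_index",
    "harary_index",
    as.vector(outer(.AC_LAGS, .AC_PROPS,
                    function(d, p) paste0("ats_", p, "_", d))),
    as.vector(outer(.AC_LAGS, .AC_PROPS,
                    function(d, p) paste0("atsc_", p, "_", d))),
    as.vector(outer(.AC_LAGS, .AC_PROPS,
                    function(d, p) paste0("geary_", p, "_", d))),
    paste0("n_pairs_dist", 1:15),
    paste0("n_hetero_pairs_dist", 1:10),
    "cc_bonds", "cn_bonds", "co_bonds", "cs_bonds", "c_halogen_bonds",
    "nn_bonds", "no_bonds", "aromatic_cc_bonds", "aromatic_cn_bonds",
    "n_ring_fusion_atoms",
    "frac_csp3", "mean_partial_charge", "max_partial_charge",
    "min_partial_charge", "sum_abs_partial_charge", "mean_atomic_mass",
    "n_implicit_h", "n_hbd_atoms", "n_hba_atoms", "n_hydrophobic_atoms",
    "mw_per_atom", "log_heavy_atom_count", "branch_fraction")
}

# BFS topological distance matrix (heavy-atom graph).
.topo_dist <- function(n, bonds) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
      adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
    }
  }
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

.descriptor_row <- function(mol, props) {
  a <- mol$atoms
  n <- mol$n_atoms
  bonds <- mol$bonds
  m <- nrow(bonds)
  el <- a$element
  deg <- a$degree
  hetero <- !(el %in% c("C", "H"))
  halogen <- el %in% c("F", "Cl", "Br", "I")
  arom <- a$aromatic
  D <- .topo_dist(n, bonds)
  Df <- D[upper.tri(D)]
  finite_pairs <- Df[is.finite(Df)]

  bond_el <- if (m) cbind(el[bonds[, 1]], el[bonds[, 2]]) else
    matrix(character(0), 0, 2)
  pair_is <- function(x, y) {
    if (m == 0L) return(0)
    sum((bond_el[, 1] == x & bond_el[, 2] == y) |
        (bond_el[, 1] == y & bond_el[, 2] == x))
  }
  arom_bond <- if (m) arom[bonds[, 1]] & arom[bonds[, 2]] & mol$ring_bond
               else logical(0)

  # neighborhood helpers
  nbrs <- vector("list", n)
  if (m) {
    for (k in seq_len(m)) {
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
  n_double_O <- vapply(seq_len(n), function(v) {
    sum(vapply(nbrs[[v]], function(k) {
      bonds[k, 3] == 2L && el[other_end(k, v)] == "O"
    }, logical(1)))
  }, numeric(1))
  adjacent_carbonyl <- vapply(seq_len(n), function(v) {
    any(vapply(nbrs[[v]], function(k) {
      w <- other_end(k, v)
      el[w] == "C" && has_double_O[w]
    }, logical(1)))
  }, logical(1))

  carbonyl_C <- el == "C" & has_double_O
  hydroxyl_O <- el == "O" & deg == 1L & a$n_implicit_h > 0 &
    !vapply(seq_len(n), function(v) {
      any(vapply(nbrs[[v]], function(k) bonds[k, 3] >= 2L, logical(1)))
    }, logical(1))
  ether_O <- el == "O" & deg == 2L & !arom &
    vapply(seq_len(n), function(v) {
      all(el[vapply(nbrs[[v]], other_end, integer(1), v = v)] == "C")
    }, logical(1))
  nitrile_C <- el == "C" &
    vapply(seq_len(n), function(v) {
      any(vapply(nbrs[[v]], function(k) {
        bonds[k, 3] == 3L && el[other_end(k, v)] == "N"
      }, logical(1)))
    }, logical(1))
  basic_N <- el == "N" & !arom & !adjacent_carbonyl & a$formal_charge >= 0 &
    vapply(seq_len(n), function(v) {
      length(nbrs[[v]]) == 0L ||
        all(vapply(nbrs[[v]], function(k) bonds[k, 3] == 1L, logical(1)))
    }, logical(1))
  amide_N <- el == "N" & adjacent_carbonyl
  sulfonyl_S <- el == "S" & n_double_O >= 2
  primary_amine <- el == "N" & a$n_implicit_h >= 2 & !arom

  # Kier-Hall deltas
  dv <- pmax(unname(.VALENCE_E[el]) - a$n_implicit_h, 0.5)
  dv[is.na(dv)] <- deg[is.na(dv)]
  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  chi0v <- sum(1 / sqrt(dv))
  chi1 <- if (m) sum(1 / sqrt(pmax(deg[bonds[, 1]] * deg[bonds[, 2]], 1)))
          else 0
  chi1v <- if (m) sum(1 / sqrt(dv[bonds[, 1]] * dv[bonds[, 2]])) else 0
  p2 <- if (n) sum(choose(deg, 2)) else 0
  p3 <- if (is.matrix(D)) sum(is.finite(Df) & Df == 3) else 0
  kappa1 <- if (m > 0) n * (n - 1)^2 / m^2 else 0
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  kappa3 <- if (p3 > 0) {
    if (n %% 2L == 1L) (n - 1) * (n - 3)^2 / p3^2
    else (n - 3)^2 * (n - 2) / p3^2
  } else 0
  ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
  srow <- rowSums(ifelse(is.finite(D), D, 0))
  gamma <- m - n + .n_components(mol)
  balaban <- if (m > 0 && all(srow[bonds[, 1]] * srow[bonds[, 2]] > 0)) {
    m / (gamma + 1) * sum(1 / sqrt(srow[bonds[, 1]] * srow[bonds[, 2]]))
  } else 0

  ac_vals <- list(mass = a$mass, charge = a$partial_charge,
                  eneg = unname(ifelse(is.na(.ELECTRONEG[el]), 2.5,
                                       .ELECTRONEG[el])),
                  degree = as.numeric(deg))
  ats <- atsc <- geary <- numeric(0)
  for (p in .AC_PROPS) {
    v <- ac_vals[[p]]
    vc <- v - mean(v)
    vv <- stats::var(v)
    for (d in .AC_LAGS) {
      sel <- which(is.finite(D) & D == d, arr.ind = TRUE)
      sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
      nd <- nrow(sel)
      ats <- c(ats, if (nd) sum(v[sel[, 1]] * v[sel[, 2]]) else 0)
      atsc <- c(atsc, if (nd) sum(vc[sel[, 1]] * vc[sel[, 2]]) else 0)
      geary <- c(geary, if (nd && isTRUE(vv > 0)) {
        sum((v[sel[, 1]] - v[sel[, 2]])^2) / (2 * nd * vv)
      } else 0)
    }
  }
  # outer() in descriptor_names() varies lag fastest within each property,
  # matching the loop order here (property outer, lag inner).

  pd <- vapply(1:15, function(d) sum(finite_pairs == d), numeric(1))
  het_idx <- which(hetero)
  hd <- vapply(1:10, function(d) {
    if (length(het_idx) < 2L) return(0)
    sub <- D[het_idx, het_idx, drop = FALSE]
    sum(sub[upper.tri(sub)] == d, na.rm = TRUE)
  }, numeric(1))

  ring_deg <- numeric(n)
  if (any(mol$ring_bond)) {
    rb <- bonds[mol$ring_bond, , drop = FALSE]
    ring_deg <- tabulate(c(rb[, 1], rb[, 2]), nbins = n)
  }
  csp3 <- el == "C" & !arom &
    vapply(seq_len(n), function(v) {
      length(nbrs[[v]]) == 0L ||
        all(vapply(nbrs[[v]], function(k) bonds[k, 3] == 1L, logical(1)))
    }, logical(1))

  c(as.numeric(props),
    molar_refractivity = mol$mr,
    heavy_atom_count = n,
    vapply(c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B"),
           function(e) sum(el == e), numeric(1)),
    count_other = sum(!el %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br",
                                 "I", "B")),
    n_bonds = m,
    n_single_bonds = sum(bonds[, 3] == 1L),
    n_double_bonds = sum(bonds[, 3] == 2L),
    n_triple_bonds = sum(bonds[, 3] == 3L),
    n_aromatic_bonds = sum(arom_bond),
    n_ring_bonds = sum(mol$ring_bond),
    n_ring_atoms = sum(a$in_ring),
    frac_ring_atoms = sum(a$in_ring) / n,
    n_aromatic_atoms = sum(arom),
    frac_aromatic_atoms = sum(arom) / n,
    n_deg1_atoms = sum(deg == 1L),
    n_deg2_atoms = sum(deg == 2L),
    n_deg3_atoms = sum(deg == 3L),
    n_deg4_atoms = sum(deg >= 4L),
    mean_degree = mean(deg),
    n_halogen = sum(halogen),
    frac_heteroatoms = sum(hetero) / n,
    n_carbonyl = sum(carbonyl_C),
    n_hydroxyl = sum(hydroxyl_O),
    n_ether = sum(ether_O),
    n_nitrile = sum(nitrile_C),
    n_primary_amine = sum(primary_amine),
    n_basic_nitrogen = sum(basic_N),
    n_amide = sum(amide_N),
    n_sulfonyl = sum(sulfonyl_S),
    n_aromatic_nitrogen = sum(el == "N" & arom),
    zagreb_m1 = sum(deg^2),
    zagreb_m2 = if (m) sum(deg[bonds[, 1]] * deg[bonds[, 2]]) else 0,
    wiener_index = sum(finite_pairs),
    balaban_j = balaban,
    chi0 = chi0, chi1 = chi1, chi0v = chi0v, chi1v = chi1v,
    kappa1 = kappa1, kappa2 = kappa2, kappa3 = kappa3,
    graph_diameter = max(ecc),
    graph_radius = min(ecc),
    mean_topological_distance =
      if (length(finite_pairs)) mean(finite_pairs) else 0,
    platt_index = if (m) sum(deg[bonds[, 1]] + deg[bonds[, 2]] - 2) else 0,
    harary_index = if (length(finite_pairs)) sum(1 / finite_pairs) else 0,
    ats, atsc, geary,
    pd, hd,
    cc_bonds = pair_is("C", "C"),
    cn_bonds = pair_is("C", "N"),
    co_bonds = pair_is("C", "O"),
    cs_bonds = pair_is("C", "S"),
    c_halogen_bonds = if (m) sum((bond_el[, 1] == "C" & halogen[bonds[, 2]]) |
                                 (bond_el[, 2] == "C" & halogen[bonds[, 1]]))
                      else 0,
    nn_bonds = pair_is("N", "N"),
    no_bonds = pair_is("N", "O"),
    aromatic_cc_bonds = if (m) sum(arom_bond & bond_el[, 1] == "C" &
                                   bond_el[, 2] == "C") else 0,
    aromatic_cn_bonds = if (m) sum(arom_bond &
                                   ((bond_el[, 1] == "C" & bond_el[, 2] == "N") |
                                    (bond_el[, 1] == "N" & bond_el[, 2] == "C")))
                        else 0,
    n_ring_fusion_atoms = sum(ring_deg >= 3),
    frac_csp3 = if (sum(el == "C")) sum(csp3) / sum(el == "C") else 0,
    mean_partial_charge = mean(a$partial_charge),
    max_partial_charge = max(a$partial_charge),
    min_partial_charge = min(a$partial_charge),
    sum_abs_partial_charge = sum(abs(a$partial_charge)),
    mean_atomic_mass = mean(a$mass),
    n_implicit_h = sum(a$n_implicit_h),
    n_hbd_atoms = sum(el %in% c("N", "O") & a$n_implicit_h > 0),
    n_hba_atoms = sum(el %in% c("N", "O")),
    n_hydrophobic_atoms = sum(el == "C" &
                              vapply(seq_len(n), function(v) {
                                !any(hetero[vapply(nbrs[[v]], other_end,
                                                   integer(1), v = v)])
                              }, logical(1))),
    mw_per_atom = props[["mw"]] / n,
    log_heavy_atom_count = log(n),
    branch_fraction = sum(deg >= 3L) / n)
}

#' Compute the pinned 2D descriptor matrix
#'
#' Computes the 209 pinned 2D descriptors (constitutional counts, functional
#' groups, topological indices, Moreau-Broto / centered / Geary
#' autocorrelations, distance distributions) for each molecule. Non-finite
#' values are replaced by 0 with a warning.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Numeric matrix, one row per molecule, columns named as in
#'   [descriptor_names()].
#' @export
descriptor_matrix <- function(smiles) {
  pin <- system.file("extdata", "descriptor_names.json",
                     package = "hergforge")
  if (nzchar(pin)) {
    pinned <- jsonlite::read_json(pin, simplifyVector = TRUE)
    if (!identical(as.character(pinned$names), descriptor_names())) {
      stop("descriptor list does not match the pinned config; ",
           "refusing to compute an incomparable matrix")
    }
  }
  mols <- parse_mols(smiles)
  props <- physchem_properties(smiles)
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  refs <- ChemmineOB::forEachMol("SMILES", src, function(m) m)
  mr <- vapply(refs, function(m) ChemmineOB::prop_OB(m)$MR, numeric(1))
  nms <- descriptor_names()
  out <- matrix(0, length(smiles), length(nms),
                dimnames = list(NULL, nms))
  for (i in seq_along(mols)) {
    mols[[i]]$mr <- mr[[i]]
    row <- .descriptor_row(mols[[i]], props[i, , drop = FALSE])
    if (length(row) != length(nms)) {
      stop("descriptor row length ", length(row), " != ", length(nms))
    }
    out[i, ] <- as.numeric(row)
  }
  if (any(!is.finite(out))) {
    warning(sum(!is.finite(out)), " non-finite descriptor value(s) set to 0")
    out[!is.finite(out)] <- 0
  }
  out
}

# Equal-frequency discretization into at most `bins` levels.
.discretize <- function(x, bins = 32L) {
  b <- min(bins, max(1L, length(unique(x))))
  if (b <= 1L) return(rep(1L, length(x)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = b + 1L),
                               names = FALSE, type = 1))
  if (length(br) <= 2L) {
    return(as.integer(factor(x <= br[1])) )
  }
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# Normalized mutual information between two discretized columns.
.nmi <- function(bx, by) {
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(1)  # constant column: fully redundant
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
  mi / sqrt(hx * hy)
}

#' Remove redundant descriptor columns by pairwise mutual information
#'
#' Discretizes each column into (up to) `bins` equal-frequency bins and
#' greedily scans columns left to right, dropping any column whose
#' normalized mutual information with an already-retained column exceeds
#' `mi_threshold`. Constant columns are dropped first with a warning. The
#' result is deterministic and invariant to row order.
#'
#' @param mat Numeric matrix (molecules x descriptors).
#' @param mi_threshold Maximum allowed normalized mutual information between
#'   retained columns (default 0.9).
#' @param bins Number of equal-frequency bins for the MI estimate.
#' @return Logical keep mask over columns.
#' @export
prune_redundant <- function(mat, mi_threshold = 0.9, bins = 32L) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, all(is.finite(mat)))
  p <- ncol(mat)
  keep <- rep(FALSE, p)
  constant <- apply(mat, 2, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warning(sum(constant), " constant descriptor column(s) dropped")
  }
  disc <- lapply(seq_len(p), function(j) .discretize(mat[, j], bins))
  kept_idx <- integer(0)
  for (j in seq_len(p)) {
    if (constant[j]) next
    redundant <- FALSE
    for (i in kept_idx) {
      if (.nmi(disc[[i]], disc[[j]]) > mi_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, j)
    }
  }
  keep
}
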