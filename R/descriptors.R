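# Per-atom electronic and topological base descriptors.
#
# All descriptors are pure functions of the 2D molecular graph (no
# coordinates, no stereo). Partial sigma charges come from the classic
# iterative partial-equalization-of-orbital-electronegativity (PEOE,
# Gasteiger-Marsili) scheme with implicit hydrogens expanded to
# pseudo-atoms; pi charges from a simple delocalization of formal charges
# over conjugated components. This keeps featurization at a fraction of a
# second per molecule.

# PEOE parameters (a, b, c) per element/hybridization key.
PEOE_PARAMS <- matrix(c(
  7.17,  6.24, -0.56,   # H
  7.98,  9.18,  1.88,   # C.3
  8.79,  9.32,  1.51,   # C.2
 10.39,  9.45,  0.73,   # C.1
 11.54, 10.82,  1.36,   # N.3
 12.87, 11.15,  0.85,   # N.2
 15.68, 11.70, -0.27,   # N.1
 14.18, 12.92,  1.39,   # O.3
 17.07, 13.79,  0.47,   # O.2
 14.66, 13.85,  2.31,   # F
 11.00,  9.69,  1.35,   # Cl
 10.08,  8.47,  1.16,   # Br
  9.90,  7.96,  0.96,   # I
 10.14,  9.13,  1.38,   # S
  8.90,  8.24,  0.96,   # P
  7.50,  6.80,  0.70,   # B
  7.30,  6.57,  0.66    # Si
), ncol = 3, byrow = TRUE,
dimnames = list(c("H", "C.3", "C.2", "C.1", "N.3", "N.2", "N.1",
                  "O.3", "O.2", "F", "Cl", "Br", "I", "S", "P", "B", "Si"),
                c("a", "b", "c")))

# Atomic hybrid polarizabilities (A^3).
ATOM_POLARIZABILITY <- c(
  H = 0.387, B = 1.600, C.3 = 1.061, C.2 = 1.352, C.1 = 1.283,
  N.3 = 0.964, N.2 = 1.030, N.1 = 0.956, O.3 = 0.637, O.2 = 0.569,
  F = 0.296, Si = 3.000, P = 1.538, S = 3.000, Cl = 2.315, Br = 3.013,
  I = 5.415
)

# Pauling electronegativities for the inductive-effect descriptor.
PAULING_EN <- c(
  H = 2.20, B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
  Si = 1.90, P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66
)

# Pi electronegativity lookup (element x unsaturation); sp3 atoms have none.
PI_EN <- c(C = 5.60, N = 7.95, O = 10.09, S = 6.22, P = 5.37, B = 5.0)

peoe_key <- function(element, hyb) {
  if (element %in% c("C", "N", "O")) {
    paste0(element, ".", max(min(hyb, 3L), 1L))
  } else element
}

# Expand implicit hydrogens to pseudo-atoms and run PEOE for n_iter cycles.
# Returns list(q = heavy-atom sigma charges, chi = converged sigma
# electronegativities of the heavy atoms).
peoe_charges <- function(mol, n_iter = 6) {
  el <- mol$atoms$element
  hyb <- atom_hybridizations(mol)
  n <- n_atoms(mol)
  keys <- vapply(seq_len(n), function(a) peoe_key(el[a], hyb[a]), character(1))
  keys[keys == "O.1"] <- "O.2"
  nh <- mol$atoms$n_h
  n_all <- n + sum(nh)
  keys_all <- c(keys, rep("H", sum(nh)))
  # bond list: heavy-heavy plus heavy-H
  bi <- mol$bonds$i; bj <- mol$bonds$j
  h_owner <- rep(seq_len(n), nh)
  if (length(h_owner) > 0) {
    bi <- c(bi, h_owner)
    bj <- c(bj, n + seq_along(h_owner))
  }
  par <- PEOE_PARAMS[keys_all, , drop = FALSE]
  q <- as.numeric(mol$atoms$charge)        # formal charges seed the iteration
  q <- c(q, rep(0, sum(nh)))
  chi_plus <- rowSums(par)                  # cation electronegativity a+b+c
  chi_plus[keys_all == "H"] <- 20.02
  chi <- par[, "a"]
  damp <- 1
  for (it in seq_len(n_iter)) {
    chi <- par[, "a"] + par[, "b"] * q + par[, "c"] * q^2
    damp <- damp * 0.5
    if (length(bi) > 0) {
      dq <- numeric(n_all)
      for (r in seq_along(bi)) {
        i <- bi[r]; j <- bj[r]
        if (chi[j] > chi[i]) {
          t <- (chi[j] - chi[i]) / chi_plus[i] * damp
          dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
        } else if (chi[i] > chi[j]) {
          t <- (chi[i] - chi[j]) / chi_plus[j] * damp
          dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
        }
      }
      q <- q + dq
    }
  }
  chi <- par[, "a"] + par[, "b"] * q + par[, "c"] * q^2
  list(q = q[seq_len(n)], chi = chi[seq_len(n)])
}

#' Names of the 14 base atomic descriptors
#'
#' The default electronic/topological descriptor set, in the fixed order
#' used by [compute_base_descriptors()]. The set is configurable in
#' [descriptor_config()] so alternative selections can be reconciled.
#'
#' @return Character vector of length 14.
#' @export
base_descriptor_names <- function() {
  c("atom_degree", "atom_valence", "hybridization", "implicit_h_count",
    "effective_polarizability", "sigma_charge", "pi_charge", "total_charge",
    "sigma_electronegativity", "pi_electronegativity", "inductive_effect",
    "atom_eccentricity", "graph_diameter", "relative_span")
}

#' Compute the base descriptors for every heavy atom of a molecule
#'
#' Returns the 14 electronic and topological descriptors (see
#' [base_descriptor_names()]) per atom:
#' heavy-atom degree; total valence (bond orders + implicit H);
#' hybridization ordinal (1 = sp, 2 = sp2/aromatic, 3 = sp3); implicit H
#' count; effective polarizability (additive atomic polarizabilities damped
#' by half per bond of distance); PEOE sigma charge; pi charge (formal
#' charge delocalized over the conjugated component); total charge;
#' converged sigma electronegativity; pi electronegativity (0 for saturated
#' atoms); inductive effect (distance-weighted electronegativity pull of the
#' rest of the molecule); topological eccentricity; graph diameter; and
#' relative span (eccentricity / diameter).
#'
#' @param mol A standardized `som_mol`.
#' @return Numeric matrix `n_atoms x 14` with descriptor names as columns.
#' @export
compute_base_descriptors <- function(mol) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  hyb <- atom_hybridizations(mol)
  deg <- lengths(atom_neighbors(mol))
  nh <- mol$atoms$n_h
  valence <- ceiling(bond_order_sums(mol)) + nh
  d <- mol_distances(mol)
  finite_d <- d; finite_d[!is.finite(finite_d)] <- 0
  ecc <- apply(finite_d, 1, max)
  diam <- max(ecc)
  span <- if (diam > 0) ecc / diam else rep(1, n)

  keys <- vapply(seq_len(n), function(a) peoe_key(el[a], hyb[a]), character(1))
  keys[keys == "O.1"] <- "O.2"
  alpha <- unname(ATOM_POLARIZABILITY[keys])
  alpha[is.na(alpha)] <- 1.0
  # effective polarizability: own + neighbors damped 0.5^distance, implicit
  # H contributes at distance 1
  damp <- 0.5^finite_d
  eff_pol <- as.numeric(damp %*% alpha) +
    as.numeric(damp %*% (nh * ATOM_POLARIZABILITY[["H"]])) * 0.5

  peoe <- peoe_charges(mol)
  # pi system: atoms that are aromatic or carry a double/triple bond
  unsat <- mol$atoms$aromatic | hyb < 3L
  pi_q <- numeric(n)
  if (any(unsat) && any(mol$atoms$charge != 0)) {
    sub <- igraph::induced_subgraph(mol_igraph(mol), which(unsat))
    comp <- igraph::components(sub)
    ids <- as.integer(igraph::V(sub)$name)
    for (k in seq_len(comp$no)) {
      members <- ids[comp$membership == k]
      fc <- sum(mol$atoms$charge[members])
      if (fc != 0) pi_q[members] <- pi_q[members] + fc / length(members)
    }
  }
  pi_en <- ifelse(unsat, unname(PI_EN[el]), 0)
  pi_en[is.na(pi_en)] <- 0

  en <- unname(PAULING_EN[el]); en[is.na(en)] <- 2.2
  ind <- numeric(n)
  if (n > 1) {
    w <- 1 / finite_d^2; diag(w) <- 0; w[!is.finite(d)] <- 0
    ind <- as.numeric(w %*% en) - en * rowSums(w)
  }

  out <- cbind(
    atom_degree = as.numeric(deg),
    atom_valence = as.numeric(valence),
    hybridization = as.numeric(hyb),
    implicit_h_count = as.numeric(nh),
    effective_polarizability = eff_pol,
    sigma_charge = peoe$q,
    pi_charge = pi_q,
    total_charge = peoe$q + pi_q,
    sigma_electronegativity = peoe$chi,
    pi_electronegativity = pi_en,
    inductive_effect = ind,
    atom_eccentricity = as.numeric(ecc),
    graph_diameter = rep(as.numeric(diam), n),
    relative_span = span
  )
  stopifnot(all(is.finite(out)))
  out
}
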