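#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number
#' @importFrom purrr map map_dbl map_int map_lgl map_chr map2 pmap
#' @importFrom stats kmeans setNames
#' @importFrom utils head read.csv write.csv
NULL

# Elements allowed in curated molecules (heavy atoms + H).
ELEMENT_WHITELIST <- c("C", "N", "S", "O", "H", "F", "Cl", "Br", "I", "P", "B", "Si")

# Monoisotopic-free average atomic masses for MW filtering.
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# Default valences used to infer implicit hydrogen counts.
DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Construct an annotated molecular graph
#'
#' A `som_mol` is the package's molecule container: a heavy-atom connection
#' table (elements, formal charges, implicit hydrogen counts, aromaticity
#' flags) plus one boolean site-of-metabolism (SoM) flag per heavy atom.
#' Stereochemistry is never stored; all structure handling is purely
#' topological (2D graph).
#'
#' @param mol_id Character identifier.
#' @param elements Character vector of heavy-atom element symbols.
#' @param bonds Data frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order` (1, 2 or 3; kekulized), and optionally a logical
#'   `aromatic` column.
#' @param charges Integer formal charges, one per atom (default all 0).
#' @param aromatic Logical per-atom aromaticity flags. If `NULL`, taken from
#'   the bond table's `aromatic` column (an atom is aromatic if it has an
#'   aromatic bond).
#' @param som Logical SoM flags, one per atom (default all `FALSE`).
#' @param provenance Character vector of source identifiers merged into this
#'   record (defaults to `mol_id`).
#' @return An object of class `som_mol`.
#' @export
som_mol <- function(mol_id, elements, bonds, charges = NULL, aromatic = NULL,
                    som = NULL, provenance = NULL) {
  n <- length(elements)
  stopifnot(n >= 1)
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= n), all(bonds$j <= n), all(bonds$i != bonds$j))
  }
  if (!"aromatic" %in% names(bonds)) bonds$aromatic <- rep(FALSE, nrow(bonds))
  # SDF aromatic bond type 4 is accepted and mapped to the aromatic flag;
  # kekulized orders (1/2/3) are preferred as they give exact H counts.
  bonds <- tibble(
    i = pmin(as.integer(bonds$i), as.integer(bonds$j)),
    j = pmax(as.integer(bonds$i), as.integer(bonds$j)),
    order = as.integer(bonds$order),
    aromatic = as.logical(bonds$aromatic) | bonds$order == 4L
  )
  charges <- as.integer(charges %||% rep(0L, n))
  if (is.null(aromatic)) {
    aromatic <- rep(FALSE, n)
    if (nrow(bonds) > 0) {
      ar <- unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))
      aromatic[ar] <- TRUE
    }
  }
  som <- as.logical(som %||% rep(FALSE, n))
  stopifnot(length(charges) == n, length(aromatic) == n, length(som) == n)
  m <- structure(
    list(
      mol_id = as.character(mol_id),
      atoms = tibble(element = as.character(elements), charge = charges,
                     aromatic = as.logical(aromatic)),
      bonds = bonds,
      som = som,
      provenance = as.character(provenance %||% mol_id)
    ),
    class = "som_mol"
  )
  m$atoms$n_h <- implicit_h_counts(m)
  m
}

#' @export
print.som_mol <- function(x, ...) {
  cat(sprintf("<som_mol> %s: %d heavy atoms, %d bonds, %d SoM, MW %.1f\n",
              x$mol_id, n_atoms(x), nrow(x$bonds), sum(x$som), mol_weight(x)))
  invisible(x)
}

#' Number of heavy atoms in a molecule
#' @param mol A `som_mol`.
#' @return Integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# Sum of bond orders incident to each atom; un-kekulized aromatic bonds
# (order 4) count 1.5.
bond_order_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  b <- mol$bonds
  if (nrow(b) > 0) {
    eff <- ifelse(b$order == 4L, 1.5, b$order)
    for (r in seq_len(nrow(b))) {
      s[b$i[r]] <- s[b$i[r]] + eff[r]
      s[b$j[r]] <- s[b$j[r]] + eff[r]
    }
  }
  s
}

# Implicit hydrogens from default valences, adjusted for formal charge.
# Cations of N gain a slot (NH4+), anions of N/O/S lose one.
implicit_h_counts <- function(mol) {
  el <- mol$atoms$element
  val <- unname(DEFAULT_VALENCE[el])
  val[is.na(val)] <- 0
  adj <- ifelse(el %in% c("N", "P") & mol$atoms$charge > 0, mol$atoms$charge,
         ifelse(mol$atoms$charge < 0, mol$atoms$charge, 0L))
  h <- val + adj - ceiling(bond_order_sums(mol))
  as.integer(pmax(0, h))
}

#' Molecular weight of a molecule (average masses, implicit H included)
#' @param mol A `som_mol`.
#' @return Weight in Dalton.
#' @export
mol_weight <- function(mol) {
  known <- mol$atoms$element %in% names(ATOMIC_MASS)
  sum(ATOMIC_MASS[mol$atoms$element[known]]) +
    sum(mol$atoms$n_h) * ATOMIC_MASS[["H"]]
}

# Heavy-atom igraph (unweighted edges; used for distances/components).
mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds) > 0) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol)))
  )
}

# Topological (bond-count) distance matrix between heavy atoms.
mol_distances <- function(mol) {
  d <- igraph::distances(mol_igraph(mol))
  # igraph orders vertices by the name column = atom index
  d[order(as.integer(rownames(d))), order(as.integer(colnames(d))), drop = FALSE]
}

# Colored graph for automorphism/canonical-form computation: atom vertices
# colored by (element, charge, nH), plus one subdivision vertex per bond
# colored by bond order (aromatic bonds share a single color so that the two
# kekule forms of an aromatic system yield the same colored graph).
mol_colored_graph <- function(mol) {
  n <- n_atoms(mol)
  at <- mol$atoms
  atom_key <- paste(at$element, at$charge, at$n_h, at$aromatic, sep = "|")
  b <- mol$bonds
  nb <- nrow(b)
  bond_key <- if (nb > 0) ifelse(b$aromatic, "bond|ar", paste0("bond|", b$order)) else character()
  keys <- c(atom_key, bond_key)
  # color ids must be invariant to atom order -> sorted key table
  colors <- as.integer(factor(keys, levels = sort(unique(keys)))) - 1L
  edges <- integer(0)
  if (nb > 0) {
    bv <- n + seq_len(nb)
    edges <- as.integer(rbind(b$i, bv, b$j, bv))
  }
  g <- igraph::make_empty_graph(n = n + nb, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  list(graph = g, colors = colors, n_atoms = n)
}

#' Topological symmetry classes of the heavy atoms
#'
#' Two atoms are equivalent iff some automorphism of the molecular graph
#' (vertices colored by element, formal charge and implicit hydrogen count;
#' bonds by order, with aromatic bonds indistinguishable from each other)
#' maps one onto the other. Orbits are computed from BLISS automorphism-group
#' generators.
#'
#' @param mol A `som_mol`.
#' @return Integer vector of class labels, one per heavy atom; equal labels
#'   mark symmetry-equivalent atoms.
#' @export
atom_symmetry_classes <- function(mol) {
  cg <- mol_colored_graph(mol)
  gens <- igraph::automorphism_group(cg$graph, colors = cg$colors)
  parent <- seq_len(cg$n_atoms)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (g in gens) {
    perm <- as.integer(g)
    for (v in seq_len(cg$n_atoms)) {
      a <- find(v); b <- find(perm[v])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(cg$n_atoms), find, integer(1))
  match(roots, unique(roots))
}

# Canonical atom order: permutation p such that atoms[p] is the canonical
# order. Identical (colored) graphs always yield the same ordered form.
canonical_atom_order <- function(mol) {
  cg <- mol_colored_graph(mol)
  lab <- igraph::canonical_permutation(cg$graph, colors = cg$colors)$labeling
  order(lab[seq_len(cg$n_atoms)])
}

# Reorder atoms of a molecule by permutation `perm` (new order = old[perm]).
permute_mol <- function(mol, perm) {
  n <- n_atoms(mol)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)
  b <- mol$bonds
  if (nrow(b) > 0) {
    b$i <- inv[b$i]; b$j <- inv[b$j]
    swap <- b$i > b$j
    tmp <- b$i[swap]; b$i[swap] <- b$j[swap]; b$j[swap] <- tmp
    b <- arrange(b, .data$i, .data$j)
  }
  m <- mol
  m$atoms <- mol$atoms[perm, ]
  m$bonds <- b
  m$som <- mol$som[perm]
  m
}

# Put a molecule into its canonical atom order.
canonicalize_mol <- function(mol) permute_mol(mol, canonical_atom_order(mol))

#' Close SoM flags under topological symmetry
#'
#' Expands every flagged atom to its full automorphism equivalence class, so
#' that symmetry-equivalent atoms always carry the same label.
#'
#' @param mol A `som_mol`.
#' @return The molecule with symmetry-closed `som` flags.
#' @export
close_som_symmetry <- function(mol) {
  if (!any(mol$som)) return(mol)
  cls <- atom_symmetry_classes(mol)
  mol$som <- cls %in% unique(cls[mol$som])
  mol
}

# Structural equality of two molecules already in canonical order (elements,
# charges, nH and the aromatic-aware bond multiset).
identical_canonical <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || nrow(a$bonds) != nrow(b$bonds)) return(FALSE)
  ak <- paste(a$atoms$element, a$atoms$charge, a$atoms$n_h, a$atoms$aromatic)
  bk <- paste(b$atoms$element, b$atoms$charge, b$atoms$n_h, b$atoms$aromatic)
  if (!identical(ak, bk)) return(FALSE)
  abk <- paste(a$bonds$i, a$bonds$j, ifelse(a$bonds$aromatic, "ar", a$bonds$order))
  bbk <- paste(b$bonds$i, b$bonds$j, ifelse(b$bonds$aromatic, "ar", b$bonds$order))
  identical(sort(abk), sort(bbk))
}

#' Bundle molecules into a library tibble
#'
#' The library container used throughout the package: one row per molecule
#' with the graph object in a list-column.
#'
#' @param mols List of `som_mol` objects.
#' @return A tibble with columns `mol_id`, `mol`, `n_atoms`, `n_som`.
#' @export
som_library <- function(mols) {
  tibble(
    mol_id = map_chr(mols, "mol_id"),
    mol = mols,
    n_atoms = map_int(mols, n_atoms),
    n_som = map_int(mols, ~ sum(.x$som))
  )
}
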