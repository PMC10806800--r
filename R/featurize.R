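# Atom featurization: Sybyl-type one-hot counts + base descriptors,
# aggregated per topological distance shell, and the circular binary atom
# fingerprint.

#' Descriptor configuration
#'
#' @param depth Maximum bond-path length `D` of the neighborhood aggregation
#'   (non-negative integer; 1, 3, 5 and 7 are the studied values, 5 the
#'   default and the recommended operating point).
#' @param base_descriptors Ordered character vector of base descriptor
#'   names; default [base_descriptor_names()].
#' @param include_sybyl Include the 24 atom-type count slots per shell
#'   (default `TRUE`).
#' @return A `descriptor_config` list with a `feature_length` field:
#'   `(24 * include_sybyl + n_base) * (depth + 1)`.
#' @export
descriptor_config <- function(depth = 5L, base_descriptors = base_descriptor_names(),
                              include_sybyl = TRUE) {
  stopifnot(depth >= 0, length(base_descriptors) >= 1)
  structure(list(
    depth = as.integer(depth),
    base_descriptors = base_descriptors,
    include_sybyl = isTRUE(include_sybyl),
    feature_length = as.integer(
      (24L * isTRUE(include_sybyl) + length(base_descriptors)) * (depth + 1L))
  ), class = "descriptor_config")
}

# Feature column names for a config: per shell d, 24 type slots then the
# base descriptors.
feature_colnames <- function(config) {
  unlist(lapply(0:config$depth, function(d) {
    c(if (config$include_sybyl) paste0("type_", sybyl_atom_types(), "_d", d),
      paste0(config$base_descriptors, "_d", d))
  }))
}

# Featurize all atoms of one molecule. Returns list(features = matrix
# n_atoms x L, fingerprint = binary matrix n_atoms x 24*(depth+1)).
featurize_mol <- function(mol, config = descriptor_config()) {
  n <- n_atoms(mol)
  D <- config$depth
  types <- sybyl_types(mol)
  type_idx <- match(types, sybyl_atom_types())
  base <- compute_base_descriptors(mol)
  base <- base[, config$base_descriptors, drop = FALSE]
  dmat <- mol_distances(mol)
  n_type <- if (config$include_sybyl) 24L else 0L
  n_base <- ncol(base)
  block <- n_type + n_base
  feats <- matrix(0, n, block * (D + 1L))
  fp <- matrix(0L, n, 24L * (D + 1L))
  for (a in seq_len(n)) {
    for (d in 0:D) {
      shell <- which(dmat[a, ] == d)
      if (length(shell) == 0) next
      off <- d * block
      if (n_type > 0) {
        counts <- tabulate(type_idx[shell], 24L)
        feats[a, off + seq_len(24L)] <- counts
        fp[a, d * 24L + which(counts > 0)] <- 1L
      } else {
        present <- unique(type_idx[shell])
        fp[a, d * 24L + present] <- 1L
      }
      feats[a, off + n_type + seq_len(n_base)] <-
        colSums(base[shell, , drop = FALSE])
    }
  }
  # Descriptors are graph functions, so automorphism-equivalent atoms must
  # have exactly equal vectors; enforce bit-exact equality (immune to
  # floating-point summation-order noise) by copying each symmetry class
  # from its first member.
  cls <- atom_symmetry_classes(mol)
  rep_row <- match(cls, cls)
  feats <- feats[rep_row, , drop = FALSE]
  fp <- fp[rep_row, , drop = FALSE]
  colnames(feats) <- feature_colnames(config)
  colnames(fp) <- paste0("fp_", rep(sybyl_atom_types(), D + 1L), "_d",
                         rep(0:D, each = 24L))
  list(features = feats, fingerprint = fp)
}

#' Featurize a single atom
#'
#' The feature vector is the concatenation over distances `d = 0..depth` of
#' the 24 atom-type counts and the element-wise sums of the base descriptors
#' over all atoms at exactly topological distance `d` from the center
#' (`d = 0` is the center atom itself).
#'
#' @param mol A standardized `som_mol`.
#' @param atom_index 1-based atom index.
#' @param config A [descriptor_config()].
#' @return List with `vector` (length `config$feature_length`),
#'   `fingerprint` (binary, length `24 * (depth+1)`) and `atom_ref`.
#' @export
featurize_atom <- function(mol, atom_index, config = descriptor_config()) {
  stopifnot(atom_index >= 1, atom_index <= n_atoms(mol))
  fz <- featurize_mol(mol, config)
  list(vector = fz$features[atom_index, ],
       fingerprint = fz$fingerprint[atom_index, ],
       atom_ref = c(mol_id = mol$mol_id, atom_index = atom_index))
}

#' Circular binary atom fingerprint
#'
#' Bit `(t, d)` is set iff at least one atom of Sybyl-style type `t` lies at
#' topological distance `d` from the center atom (`d = 0` encodes the
#' center's own type). Length `24 * (depth + 1)`.
#'
#' @param mol A `som_mol`.
#' @param atom_index 1-based atom index.
#' @param depth Maximum bond-path length (default 5).
#' @return Integer 0/1 vector.
#' @export
fame_fingerprint <- function(mol, atom_index, depth = 5L) {
  cfg <- descriptor_config(depth = depth)
  featurize_atom(mol, atom_index, cfg)$fingerprint
}

#' Featurize every heavy atom of a library
#'
#' Produces the atom-record table consumed by the splitting, modeling and
#' active-learning layers: one row per heavy atom with the aggregated
#' descriptor vector and the circular fingerprint held in matrix columns.
#'
#' @param library A curated library tibble.
#' @param config A [descriptor_config()].
#' @return A tibble with columns `record_id` (integer), `mol_id`,
#'   `atom_index` (1-based), `atom_refs` (list of `"mol_id:atom_index"`
#'   strings, length > 1 after deduplication), `is_som`, `features` (matrix
#'   column) and `fingerprint` (matrix column). The config is attached as
#'   attribute `descriptor_config`.
#' @export
featurize_library <- function(library, config = descriptor_config()) {
  parts <- map(seq_len(nrow(library)), function(k) {
    mol <- library$mol[[k]]
    fz <- featurize_mol(mol, config)
    tibble(
      mol_id = mol$mol_id,
      atom_index = seq_len(n_atoms(mol)),
      atom_refs = as.list(paste0(mol$mol_id, ":", seq_len(n_atoms(mol)))),
      is_som = mol$som,
      features = fz$features,
      fingerprint = fz$fingerprint
    )
  })
  out <- bind_rows(parts)
  # row-binding drops matrix-column dimnames; restore them
  colnames(out$features) <- feature_colnames(config)
  colnames(out$fingerprint) <- paste0("fp_", rep(sybyl_atom_types(), config$depth + 1L),
                                      "_d", rep(0:config$depth, each = 24L))
  out <- mutate(out, record_id = row_number(), .before = 1)
  attr(out, "descriptor_config") <- config
  out
}

#' Tanimoto similarity between binary fingerprints
#'
#' @param a,b Binary vectors of equal length, or `b` a matrix with
#'   fingerprints in rows.
#' @return Similarity in `[0, 1]`; 1 when both fingerprints are empty.
#' @export
tanimoto <- function(a, b) {
  if (is.matrix(b)) {
    inter <- as.numeric(b %*% a)
    uni <- sum(a) + rowSums(b) - inter
    return(ifelse(uni == 0, 1, inter / uni))
  }
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) 1 else inter / uni
}

# All-pairs Tanimoto similarity matrix for a binary fingerprint matrix.
tanimoto_matrix <- function(fp) {
  inter <- tcrossprod(fp)
  sizes <- rowSums(fp)
  uni <- outer(sizes, sizes, "+") - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  diag(s) <- 1
  s
}
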