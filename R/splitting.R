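# Atom-level deduplication and fold generation for cross-validated active
# learning.

#' Merge atoms with identical descriptor vectors
#'
#' Atoms whose full aggregated descriptor vectors are bit-exact equal are
#' merged into a single record (`atom_refs` concatenated). Under the
#' deterministic featurization pipeline such duplicates are topologically
#' symmetric atoms, so their labels agree; a label conflict raises an error
#' unless `on_conflict = "keep_positive"`.
#'
#' Idempotent and order-independent (up to `atom_refs` order).
#'
#' @param atoms Atom-record tibble from [featurize_library()].
#' @param on_conflict `"error"` (default) or `"keep_positive"`.
#' @return Deduplicated atom-record tibble, `record_id` renumbered.
#' @export
deduplicate_atoms <- function(atoms, on_conflict = c("error", "keep_positive")) {
  on_conflict <- match.arg(on_conflict)
  # full-precision key so that grouping is bit-exact, no tolerance
  key <- apply(atoms$features, 1, function(v) paste(sprintf("%.17g", v), collapse = ","))
  grp <- match(key, unique(key))
  keep <- !duplicated(grp)
  out <- atoms[keep, ]
  out$atom_refs <- map(unique(grp), function(g) {
    unlist(atoms$atom_refs[grp == g], use.names = FALSE)
  })
  label_sets <- map(unique(grp), ~ unique(atoms$is_som[grp == .x]))
  conflict <- map_lgl(label_sets, ~ length(.x) > 1)
  if (any(conflict)) {
    if (on_conflict == "error") {
      abort(sprintf("label conflict among %d group(s) of identical descriptor vectors",
                    sum(conflict)))
    }
    out$is_som[conflict] <- TRUE
  }
  out$record_id <- seq_len(nrow(out))
  attr(out, "descriptor_config") <- attr(atoms, "descriptor_config")
  out
}

#' Stratified k-fold assignment of atom records
#'
#' Shuffles each class with the given seed and deals records round-robin, so
#' per-fold class counts differ from exact proportionality by at most one.
#'
#' @param atoms Atom-record tibble.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; same seed, same assignment.
#' @return Fold tibble: `record_id`, `mol_id`, `atom_index`, `fold` (in
#'   `1..k`), `scheme`, `seed`.
#' @export
stratified_folds <- function(atoms, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  if (min(table(atoms$is_som)) < k || length(unique(atoms$is_som)) < 2) {
    abort("each class needs at least k members for stratified folds")
  }
  withr::local_seed(as.integer(seed))
  fold <- integer(nrow(atoms))
  offset <- 0L
  for (lbl in c(TRUE, FALSE)) {
    idx <- which(atoms$is_som == lbl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  tibble(record_id = atoms$record_id, mol_id = atoms$mol_id,
         atom_index = atoms$atom_index, fold = fold,
         scheme = "stratified", seed = as.integer(seed))
}

#' Butina clustering of binary fingerprints
#'
#' Leader-style sphere-exclusion clustering: candidate centroids are ordered
#' by neighbor count at the similarity cutoff (ties by record index); each
#' centroid claims its unassigned neighbors. A union-find post-pass then
#' merges any clusters still linked by a pair at or above the cutoff, so the
#' final clustering guarantees that every pair with similarity above the
#' cutoff shares a cluster.
#'
#' @param fp Binary fingerprint matrix (records in rows).
#' @param similarity_cutoff Tanimoto similarity threshold (pairs `>=` cutoff
#'   are neighbors); equivalently a distance cutoff of `1 - cutoff`.
#' @return Integer cluster labels (1-based, densest cluster first).
#' @export
butina_cluster <- function(fp, similarity_cutoff = 0.80) {
  n <- nrow(fp)
  s <- tanimoto_matrix(fp)
  nbr <- s >= similarity_cutoff
  diag(nbr) <- FALSE
  counts <- rowSums(nbr)
  ord <- order(-counts, seq_len(n))
  cluster <- integer(n)
  cid <- 0L
  for (c0 in ord) {
    if (cluster[c0] != 0L) next
    cid <- cid + 1L
    members <- c(c0, which(nbr[c0, ] & cluster == 0L))
    cluster[members] <- cid
  }
  # guarantee pass: merge clusters linked by any neighbor pair
  parent <- seq_len(cid)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  links <- which(nbr & upper.tri(nbr), arr.ind = TRUE)
  if (nrow(links) > 0) {
    for (r in seq_len(nrow(links))) {
      a <- find(cluster[links[r, 1]]); b <- find(cluster[links[r, 2]])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(cluster, find, integer(1))
  match(roots, unique(roots))
}

#' Similarity-clustered k-fold assignment
#'
#' Clusters atom environments (circular fingerprints at `fp_depth`) with
#' [butina_cluster()] at distance cutoff `1 - similarity_ceiling`, then
#' packs whole clusters into `k` folds greedily (largest cluster first, into
#' the currently smallest fold). Guarantees that no cross-fold atom pair
#' exceeds the Tanimoto `similarity_ceiling`.
#'
#' @param atoms Atom-record tibble (must carry `fingerprint` computed at
#'   `fp_depth`).
#' @param k Number of folds.
#' @param similarity_ceiling Maximum allowed cross-fold Tanimoto similarity
#'   (default 0.80).
#' @param fp_depth Fingerprint bond-path length the records were featurized
#'   at (default 5); checked against the attached descriptor config.
#' @return Fold tibble as in [stratified_folds()], `scheme =
#'   "similarity_cluster"`.
#' @export
cluster_folds <- function(atoms, k = 5L, similarity_ceiling = 0.80, fp_depth = 5L) {
  stopifnot(k >= 2, similarity_ceiling > 0, similarity_ceiling <= 1)
  cfg <- attr(atoms, "descriptor_config")
  if (!is.null(cfg) && cfg$depth != fp_depth) {
    abort(sprintf("records were featurized at depth %d, not fp_depth = %d",
                  cfg$depth, fp_depth))
  }
  cluster <- butina_cluster(atoms$fingerprint, similarity_cutoff = similarity_ceiling)
  n_cluster <- max(cluster)
  if (n_cluster < k) {
    abort(sprintf("cannot form %d dissimilar folds: only %d clusters at ceiling %.2f",
                  k, n_cluster, similarity_ceiling))
  }
  sizes <- tabulate(cluster, n_cluster)
  fold_of_cluster <- integer(n_cluster)
  fold_sizes <- numeric(k)
  for (cl in order(-sizes, seq_len(n_cluster))) {
    f <- which.min(fold_sizes)
    fold_of_cluster[cl] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[cl]
  }
  tibble(record_id = atoms$record_id, mol_id = atoms$mol_id,
         atom_index = atoms$atom_index, fold = fold_of_cluster[cluster],
         scheme = "similarity_cluster", seed = NA_integer_)
}

#' Maximum cross-fold fingerprint similarity (brute force)
#'
#' Verification helper for similarity-clustered folds: computes the maximum
#' Tanimoto similarity over all pairs of records assigned to different
#' folds.
#'
#' @param atoms Atom-record tibble with a `fingerprint` column.
#' @param folds Fold tibble aligned with `atoms` by `record_id`.
#' @return A single number in `[0, 1]`.
#' @export
max_cross_fold_similarity <- function(atoms, folds) {
  fold <- folds$fold[match(atoms$record_id, folds$record_id)]
  s <- tanimoto_matrix(atoms$fingerprint)
  cross <- outer(fold, fold, "!=")
  if (!any(cross)) return(0)
  max(s[cross])
}
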