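# Library curation: standardization, eligibility filtering, symmetry-aware
# duplicate merging, and the bookkeeping report.

#' Standardize a molecule
#'
#' Keeps the largest organic component (most heavy atoms; ties broken by
#' carbon count, then by first occurrence), neutralizes simple formal
#' charges (protonated amines lose a hydrogen, deprotonated N/O/S acids gain
#' one; quaternary centers and unneutralizable charges are kept), and puts
#' the atoms into the canonical order used by all downstream modules. SoM
#' flags are remapped through every step. Stereochemistry is already absent
#' from the graph container, so no stereo handling is needed here.
#'
#' An error is raised if a SoM annotation sits on a removed (salt) component,
#' because the annotation would otherwise be lost silently.
#'
#' @param mol A `som_mol`.
#' @return The standardized `som_mol`. Idempotent.
#' @export
standardize_mol <- function(mol) {
  comp <- igraph::components(mol_igraph(mol))
  if (comp$no > 1) {
    n_c <- vapply(seq_len(comp$no), function(k) {
      idx <- which(comp$membership == k)
      sum(mol$atoms$element[idx] == "C") * 1000 + length(idx)
    }, numeric(1))
    sizes <- tabulate(comp$membership, comp$no)
    keep_comp <- which.max(sizes * 100000 + n_c)
    keep <- which(comp$membership == keep_comp)
    if (any(mol$som[-keep])) {
      abort(sprintf("molecule '%s': SoM annotation on a removed salt component",
                    mol$mol_id))
    }
    remap <- match(seq_len(n_atoms(mol)), keep)
    b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, ]
    b$i <- remap[b$i]; b$j <- remap[b$j]
    mol <- som_mol(mol$mol_id, mol$atoms$element[keep], b,
                   charges = mol$atoms$charge[keep],
                   aromatic = mol$atoms$aromatic[keep],
                   som = mol$som[keep], provenance = mol$provenance)
  }
  # simple charge neutralization
  ch <- mol$atoms$charge
  nh <- mol$atoms$n_h
  el <- mol$atoms$element
  for (a in seq_len(n_atoms(mol))) {
    if (ch[a] > 0 && nh[a] >= ch[a] && el[a] %in% c("N", "O", "S", "P")) {
      ch[a] <- 0L           # e.g. R-NH3+ -> R-NH2
    } else if (ch[a] < 0 && el[a] %in% c("N", "O", "S")) {
      ch[a] <- 0L           # e.g. R-O- -> R-OH
    }
  }
  if (!identical(ch, mol$atoms$charge)) {
    mol <- som_mol(mol$mol_id, el, mol$bonds, charges = ch,
                   aromatic = mol$atoms$aromatic, som = mol$som,
                   provenance = mol$provenance)
  }
  canonicalize_mol(mol)
}

#' Test a molecule against the curation eligibility rules
#'
#' A molecule is eligible iff (1) it has at least one SoM flag, (2) all
#' heavy atoms are in the element whitelist (C, N, S, O, F, Cl, Br, I, P, B,
#' Si), (3) its molecular weight lies in the inclusive range 100-1000 Da,
#' and (4) it parsed into a non-empty graph. The first violated rule is
#' named.
#'
#' @param mol A standardized `som_mol`.
#' @return A list with `accepted` (logical) and `rule` (name of the first
#'   violated rule, or `NA`).
#' @export
filter_eligible <- function(mol) {
  rule <- NA_character_
  if (n_atoms(mol) == 0) rule <- "parsable"
  else if (!any(mol$som)) rule <- "has_som"
  else if (!all(mol$atoms$element %in% ELEMENT_WHITELIST)) rule <- "element_whitelist"
  else {
    mw <- mol_weight(mol)
    if (mw < 100 || mw > 1000) rule <- "molecular_weight"
  }
  list(accepted = is.na(rule), rule = rule)
}

#' Merge duplicate structures and close annotations under symmetry
#'
#' Molecules with identical standard InChI are collapsed into a single
#' record whose SoM flags are the union over all duplicates (atom indices
#' are directly compatible because every standardized molecule is in
#' canonical atom order), then expanded to full automorphism equivalence
#' classes. Records whose InChI cannot be generated are dropped with a
#' warning; records that share an InChI but have non-identical canonical
#' graphs (e.g. exotic tautomer collisions) are kept unmerged with a
#' warning.
#'
#' @param mols List of standardized `som_mol` objects (canonical atom
#'   order).
#' @return List of merged `som_mol` objects, each with symmetry-closed
#'   flags; `provenance` records the source ids.
#' @export
merge_duplicates <- function(mols) {
  inchis <- map_chr(mols, mol_inchi)
  bad <- is.na(inchis)
  if (any(bad)) {
    warn(sprintf("dropping %d record(s) with InChI generation failure", sum(bad)))
    mols <- mols[!bad]; inchis <- inchis[!bad]
  }
  out <- list()
  for (key in unique(inchis)) {
    grp <- mols[inchis == key]
    rep_mol <- grp[[1]]
    if (length(grp) > 1) {
      for (other in grp[-1]) {
        if (!identical_canonical(rep_mol, other)) {
          warn(sprintf("InChI collision with non-identical graphs ('%s' vs '%s'); not merged",
                       rep_mol$mol_id, other$mol_id))
          other <- close_som_symmetry(other)
          out[[length(out) + 1]] <- other
          next
        }
        rep_mol$som <- rep_mol$som | other$som
        rep_mol$provenance <- c(rep_mol$provenance, other$provenance)
      }
    }
    out[[length(out) + 1]] <- close_som_symmetry(rep_mol)
  }
  out
}

#' Curate an annotated molecule library
#'
#' Runs the full pipeline: standardization (salt stripping, charge
#' normalization, canonical atom order), eligibility filtering (at least one
#' SoM, element whitelist, molecular weight 100-1000 Da inclusive), InChI
#' duplicate merging with symmetry closure of the SoM flags. The pipeline is
#' idempotent: curating a curated library returns it unchanged.
#'
#' @param library A library tibble from [read_som_library()],
#'   [som_library()] or [generate_library()].
#' @return The curated library tibble, sorted by `mol_id`, with a
#'   `curation_report` attribute (see [curation_report()]).
#' @export
curate_library <- function(library) {
  n_input <- nrow(library)
  std <- list()
  rejected <- c(parsable = 0L, has_som = 0L, element_whitelist = 0L,
                molecular_weight = 0L, standardization = 0L)
  for (k in seq_len(nrow(library))) {
    m <- tryCatch(standardize_mol(library$mol[[k]]), error = function(e) {
      warn(sprintf("standardization failed for '%s': %s",
                   library$mol_id[k], conditionMessage(e)))
      NULL
    })
    if (is.null(m)) { rejected[["standardization"]] <- rejected[["standardization"]] + 1L; next }
    f <- filter_eligible(m)
    if (!f$accepted) { rejected[[f$rule]] <- rejected[[f$rule]] + 1L; next }
    std[[length(std) + 1]] <- m
  }
  merged <- merge_duplicates(std)
  n_merged_away <- length(std) - length(merged)
  out <- som_library(merged)
  out <- arrange(out, .data$mol_id)
  attr(out, "curation_report") <- tibble(
    n_input = n_input,
    n_rejected = sum(rejected),
    n_rejected_parsable = rejected[["parsable"]] + rejected[["standardization"]],
    n_rejected_has_som = rejected[["has_som"]],
    n_rejected_element_whitelist = rejected[["element_whitelist"]],
    n_rejected_molecular_weight = rejected[["molecular_weight"]],
    n_merged_duplicates = n_merged_away,
    n_output = nrow(out)
  )
  out
}

#' Retrieve the curation report of a curated library
#'
#' @param library A tibble returned by [curate_library()].
#' @return One-row tibble of input/rejection/merge/output counts satisfying
#'   `n_output = n_input - n_rejected - n_merged_duplicates`.
#' @export
curation_report <- function(library) {
  rep <- attr(library, "curation_report")
  if (is.null(rep)) abort("library carries no curation report; run curate_library() first")
  rep
}
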