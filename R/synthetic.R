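# Synthetic annotated molecule libraries.
#
# Drug-like toy molecules are assembled from a fixed scaffold + substituent
# grammar (aromatic and saturated rings, N/O/S heteroatoms, alkyl chains,
# halogens -- whitelist elements only) and labeled by deterministic
# substructure rules that loosely mimic common metabolic hotspots
# (O/N-dealkylation, S-oxidation, aromatic hydroxylation para to an
# electron donor). The rules make labels a deterministic function of the
# graph -- statistical realism, not metabolic truth. The library's
# statistical shape targets a real-world SoM corpus: about 2.6 SoMs per
# molecule and a SoM fraction of about 0.11 among heavy atoms.

# -- fragment grammar ---------------------------------------------------

# A fragment: list(elements, bonds tibble(i,j,order,aromatic), open =
# indices eligible for substitution/linkage).
frag_ring <- function(kind) {
  switch(kind,
    benzene = list(
      elements = rep("C", 6),
      bonds = tibble(i = 1:6, j = c(2:6, 1), order = c(1L, 2L, 1L, 2L, 1L, 2L),
                     aromatic = TRUE),
      open = 1:6),
    pyridine = list(
      elements = c("N", rep("C", 5)),
      bonds = tibble(i = 1:6, j = c(2:6, 1), order = c(1L, 2L, 1L, 2L, 1L, 2L),
                     aromatic = TRUE),
      open = 2:6),
    pyrimidine = list(
      elements = c("N", "C", "N", "C", "C", "C"),
      bonds = tibble(i = 1:6, j = c(2:6, 1), order = c(2L, 1L, 2L, 1L, 2L, 1L),
                     aromatic = TRUE),
      open = c(2, 4, 5, 6)),
    thiophene = list(
      elements = c("S", rep("C", 4)),
      bonds = tibble(i = 1:5, j = c(2:5, 1), order = c(1L, 2L, 1L, 2L, 1L),
                     aromatic = TRUE),
      open = 2:5),
    furan = list(
      elements = c("O", rep("C", 4)),
      bonds = tibble(i = 1:5, j = c(2:5, 1), order = c(1L, 2L, 1L, 2L, 1L),
                     aromatic = TRUE),
      open = 2:5),
    cyclohexane = list(
      elements = rep("C", 6),
      bonds = tibble(i = 1:6, j = c(2:6, 1), order = 1L, aromatic = FALSE),
      open = 1:6),
    piperidine = list(
      elements = c("N", rep("C", 5)),
      bonds = tibble(i = 1:6, j = c(2:6, 1), order = 1L, aromatic = FALSE),
      open = 1:6)
  )
}

RING_KINDS <- c(benzene = 0.40, pyridine = 0.17, pyrimidine = 0.09,
                thiophene = 0.05, furan = 0.05, cyclohexane = 0.16,
                piperidine = 0.08)

# Substituents: elements/bonds of the group, atom 1 binds to the host.
frag_sub <- function(kind) {
  tb <- function(...) tibble(...)
  switch(kind,
    methyl = list(elements = "C", bonds = tb(i = integer(), j = integer(), order = integer(), aromatic = logical())),
    ethyl = list(elements = c("C", "C"), bonds = tb(i = 1L, j = 2L, order = 1L, aromatic = FALSE)),
    hydroxy = list(elements = "O", bonds = tb(i = integer(), j = integer(), order = integer(), aromatic = logical())),
    amino = list(elements = "N", bonds = tb(i = integer(), j = integer(), order = integer(), aromatic = logical())),
    methoxy = list(elements = c("O", "C"), bonds = tb(i = 1L, j = 2L, order = 1L, aromatic = FALSE)),
    ethoxy = list(elements = c("O", "C", "C"), bonds = tb(i = c(1L, 2L), j = c(2L, 3L), order = 1L, aromatic = FALSE)),
    dimethylamino = list(elements = c("N", "C", "C"), bonds = tb(i = c(1L, 1L), j = c(2L, 3L), order = 1L, aromatic = FALSE)),
    methylthio = list(elements = c("S", "C"), bonds = tb(i = 1L, j = 2L, order = 1L, aromatic = FALSE)),
    fluoro = list(elements = "F", bonds = tb(i = integer(), j = integer(), order = integer(), aromatic = logical())),
    chloro = list(elements = "Cl", bonds = tb(i = integer(), j = integer(), order = integer(), aromatic = logical())),
    bromo = list(elements = "Br", bonds = tb(i = integer(), j = integer(), order = integer(), aromatic = logical())),
    acetyl = list(elements = c("C", "O", "C"), bonds = tb(i = c(1L, 1L), j = c(2L, 3L), order = c(2L, 1L), aromatic = FALSE)),
    carboxamide = list(elements = c("C", "O", "N"), bonds = tb(i = c(1L, 1L), j = c(2L, 3L), order = c(2L, 1L), aromatic = FALSE)),
    carboxyl = list(elements = c("C", "O", "O"), bonds = tb(i = c(1L, 1L), j = c(2L, 3L), order = c(2L, 1L), aromatic = FALSE)),
    trifluoromethyl = list(elements = c("C", "F", "F", "F"),
                           bonds = tb(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L), order = 1L, aromatic = FALSE))
  )
}

SUB_KINDS <- c(methyl = 0.15, ethyl = 0.08, hydroxy = 0.06, amino = 0.05,
               methoxy = 0.11, ethoxy = 0.04, dimethylamino = 0.06,
               methylthio = 0.04, fluoro = 0.08, chloro = 0.08, bromo = 0.04,
               acetyl = 0.07, carboxamide = 0.06, carboxyl = 0.05,
               trifluoromethyl = 0.06)

# Attach a fragment to atom `host` of a growing graph via a single bond to
# the fragment's `frag_atom` (default its first atom).
attach_fragment <- function(g, frag, host, frag_atom = 1L) {
  off <- length(g$elements)
  fb <- frag$bonds
  if (nrow(fb) > 0) { fb$i <- fb$i + off; fb$j <- fb$j + off }
  g$elements <- c(g$elements, frag$elements)
  g$bonds <- bind_rows(
    g$bonds, fb,
    tibble(i = host, j = off + frag_atom, order = 1L, aromatic = FALSE)
  )
  g$open <- c(g$open, if (!is.null(frag$open)) frag$open + off)
  g
}

# Count of hydrogens still available on atom `a` of the growing graph
# (keeps substitution chemically valid).
free_valence <- function(g, a) {
  el <- g$elements[a]
  val <- DEFAULT_VALENCE[[el]] %||% 0
  eff <- sum(ifelse(g$bonds$aromatic[g$bonds$i == a | g$bonds$j == a], 1.5,
                    g$bonds$order[g$bonds$i == a | g$bonds$j == a]))
  max(0, val - ceiling(eff))
}

# Sample one raw molecule from the grammar.
sample_molecule <- function(mol_id) {
  g <- frag_ring(sample(names(RING_KINDS), 1, prob = RING_KINDS))
  n_ring <- 1L + (stats::runif(1) < 0.85) + (stats::runif(1) < 0.35)
  for (rr in seq_len(n_ring - 1L)) {   # extra rings, directly linked or via CH2
    avail <- g$open[vapply(g$open, function(a) free_valence(g, a) >= 1, logical(1))]
    if (length(avail) == 0) break
    host <- avail[sample.int(length(avail), 1)]
    if (stats::runif(1) < 0.4) {
      g <- attach_fragment(g, list(elements = "C",
                                   bonds = tibble(i = integer(), j = integer(),
                                                  order = integer(), aromatic = logical())),
                           host)
      host <- length(g$elements)
    }
    ring2 <- frag_ring(sample(names(RING_KINDS), 1, prob = RING_KINDS))
    link <- ring2$open[sample.int(length(ring2$open), 1)]
    g <- attach_fragment(g, ring2, host, frag_atom = link)
  }
  n_sub <- sample(1:4, 1, prob = c(0.15, 0.35, 0.30, 0.20))
  for (s in seq_len(n_sub)) {
    avail <- g$open[vapply(g$open, function(a) free_valence(g, a) >= 1, logical(1))]
    if (length(avail) == 0) break
    host <- avail[sample.int(length(avail), 1)]
    g <- attach_fragment(g, frag_sub(sample(names(SUB_KINDS), 1, prob = SUB_KINDS)),
                         host)
  }
  som_mol(mol_id, g$elements, g$bonds[, c("i", "j", "order", "aromatic")])
}

# -- labeling rules -----------------------------------------------------

#' Default synthetic SoM labeling rules
#'
#' An ordered set of named substructure matchers; an atom is a synthetic SoM
#' iff at least one rule matches it. Each rule is a function
#' `som_mol -> integer atom indices`:
#' \describe{
#'   \item{o_dealkylation}{sp3 carbon with at least one H bonded to an
#'     ether-type oxygen (two heavy neighbors).}
#'   \item{n_dealkylation}{sp3 carbon with at least one H bonded to a
#'     neutral sp3 (non-amide) nitrogen.}
#'   \item{s_oxidation}{divalent sulfur without oxo substituents.}
#'   \item{aromatic_hydroxylation}{aromatic CH at topological distance 4
#'     from an O/N donor directly attached to an aromatic carbon (the para
#'     position of activated rings).}
#' }
#'
#' @return Named list of matcher functions.
#' @export
default_som_rules <- function() {
  list(
    o_dealkylation = function(mol) {
      nbrs <- atom_neighbors(mol)
      hyb <- atom_hybridizations(mol)
      el <- mol$atoms$element
      which(vapply(seq_len(n_atoms(mol)), function(a) {
        el[a] == "C" && hyb[a] == 3L && mol$atoms$n_h[a] >= 1 &&
          any(el[nbrs[[a]]] == "O" & lengths(nbrs[nbrs[[a]]]) == 2L &
                !mol$atoms$aromatic[nbrs[[a]]])
      }, logical(1)))
    },
    n_dealkylation = function(mol) {
      nbrs <- atom_neighbors(mol)
      hyb <- atom_hybridizations(mol)
      el <- mol$atoms$element
      amide_n <- vapply(seq_len(n_atoms(mol)), function(a) {
        el[a] == "N" && any(vapply(nbrs[[a]], function(x) {
          el[x] == "C" && any(el[nbrs[[x]]] == "O" &
            vapply(nbrs[[x]], function(o) any(mol$bonds$order[
              (mol$bonds$i == x & mol$bonds$j == o) |
              (mol$bonds$j == x & mol$bonds$i == o)] == 2L), logical(1)))
        }, logical(1)))
      }, logical(1))
      which(vapply(seq_len(n_atoms(mol)), function(a) {
        el[a] == "C" && hyb[a] == 3L && mol$atoms$n_h[a] >= 1 &&
          any(el[nbrs[[a]]] == "N" & hyb[nbrs[[a]]] == 3L &
                mol$atoms$charge[nbrs[[a]]] == 0L &
                !mol$atoms$aromatic[nbrs[[a]]] & !amide_n[nbrs[[a]]])
      }, logical(1)))
    },
    s_oxidation = function(mol) {
      nbrs <- atom_neighbors(mol)
      el <- mol$atoms$element
      which(vapply(seq_len(n_atoms(mol)), function(a) {
        el[a] == "S" && length(nbrs[[a]]) <= 2L &&
          !any(el[nbrs[[a]]] == "O")
      }, logical(1)))
    },
    aromatic_hydroxylation = function(mol) {
      el <- mol$atoms$element
      arom <- mol$atoms$aromatic
      nbrs <- atom_neighbors(mol)
      donors <- which(el %in% c("O", "N") & !arom &
                        vapply(seq_len(n_atoms(mol)),
                               function(a) any(arom[nbrs[[a]]]), logical(1)))
      if (length(donors) == 0) return(integer())
      d <- mol_distances(mol)
      which(vapply(seq_len(n_atoms(mol)), function(a) {
        el[a] == "C" && arom[a] && mol$atoms$n_h[a] >= 1 &&
          any(d[a, donors] == 4)
      }, logical(1)))
    }
  )
}

#' Apply labeling rules to a molecule
#'
#' @param mol A standardized `som_mol`.
#' @param rules Named list of matcher functions (default
#'   [default_som_rules()]).
#' @return Logical SoM flags (union of all rule matches, closed under
#'   topological symmetry).
#' @export
label_soms <- function(mol, rules = default_som_rules()) {
  if (!all(vapply(rules, is.function, logical(1)))) {
    abort("every labeling rule must be a function(som_mol) -> atom indices")
  }
  flags <- rep(FALSE, n_atoms(mol))
  for (r in rules) {
    idx <- r(mol)
    if (length(idx) > 0) {
      stopifnot(all(idx >= 1 & idx <= n_atoms(mol)))
      flags[idx] <- TRUE
    }
  }
  mol$som <- flags
  close_som_symmetry(mol)$som
}

#' Generate a synthetic annotated molecule library
#'
#' Draws molecules from the scaffold + substituent grammar, standardizes
#' them, labels SoMs with `rules`, and resamples any molecule that fails
#' the eligibility criteria (no SoM, MW outside 100-1000 Da). Deterministic
#' given the seed. For libraries of a few hundred molecules the heavy-atom
#' SoM fraction lands near 0.11 and the mean SoM count per molecule near
#' 2.6, the statistical shape of expert-curated SoM corpora.
#'
#' @param n_molecules Number of molecules (>= 1).
#' @param seed Integer seed.
#' @param rules Labeling rule set (default [default_som_rules()]).
#' @param max_attempts Resampling budget per molecule before erroring.
#' @return A curated-shape library tibble (see [som_library()]); molecules
#'   are standardized, eligible and symmetry-closed by construction.
#' @export
generate_library <- function(n_molecules, seed = 1L,
                             rules = default_som_rules(), max_attempts = 50L) {
  stopifnot(n_molecules >= 1)
  withr::local_seed(as.integer(seed))
  mols <- vector("list", n_molecules)
  for (k in seq_len(n_molecules)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      m <- standardize_mol(sample_molecule(sprintf("synth%04d", k)))
      m$som <- label_soms(m, rules)
      if (filter_eligible(m)$accepted) { ok <- TRUE; break }
    }
    if (!ok) abort("grammar exhaustion: could not sample an eligible molecule")
    mols[[k]] <- m
  }
  som_library(mols)
}
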