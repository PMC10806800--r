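# Sybyl-style atom typing: 24 fixed categories combining element and
# hybridization/environment, covering the curation element whitelist.

SYBYL_TYPES <- c(
  "C.3", "C.2", "C.1", "C.ar",
  "N.3", "N.2", "N.1", "N.ar", "N.am", "N.4",
  "O.3", "O.2", "O.co2",
  "S.3", "S.2", "S.o", "S.o2",
  "P.3",
  "F", "Cl", "Br", "I",
  "B.3", "Si.3"
)

#' The atom-type category table
#'
#' @return Character vector of the 24 Sybyl-style atom-type codes used by
#'   the descriptor and fingerprint layers, in their fixed bit order.
#' @export
sybyl_atom_types <- function() SYBYL_TYPES

# Hybridization ordinal per atom: 1 = sp, 2 = sp2 (incl. aromatic), 3 = sp3.
atom_hybridizations <- function(mol) {
  hyb <- rep(3L, n_atoms(mol))
  b <- mol$bonds
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      o <- b$order[r]
      if (b$aromatic[r] || o == 2L) {
        hyb[b$i[r]] <- pmin(hyb[b$i[r]], 2L)
        hyb[b$j[r]] <- pmin(hyb[b$j[r]], 2L)
      }
      if (o == 3L) hyb[c(b$i[r], b$j[r])] <- 1L
    }
    # cumulated double bonds (allenes, SO2...) -> sp for C
    dbl <- tabulate(c(b$i[b$order == 2L], b$j[b$order == 2L]), n_atoms(mol))
    hyb[dbl >= 2 & mol$atoms$element == "C"] <- 1L
  }
  hyb
}

# Neighbor list per atom.
atom_neighbors <- function(mol) {
  nbrs <- rep(list(integer()), n_atoms(mol))
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    nbrs[[b$i[r]]] <- c(nbrs[[b$i[r]]], b$j[r])
    nbrs[[b$j[r]]] <- c(nbrs[[b$j[r]]], b$i[r])
  }
  nbrs
}

#' Sybyl-style atom types for all heavy atoms of a molecule
#'
#' Assigns each heavy atom one of the 24 categories from
#' [sybyl_atom_types()] based on element, hybridization, aromaticity and
#' functional environment (amide nitrogen, carboxylate oxygen, sulfoxide /
#' sulfone sulfur, quaternary nitrogen).
#'
#' @param mol A `som_mol` whose elements are all in the whitelist.
#' @return Character vector of type codes, one per heavy atom.
#' @export
sybyl_types <- function(mol) {
  el <- mol$atoms$element
  if (!all(el %in% setdiff(ELEMENT_WHITELIST, "H"))) {
    abort(sprintf("unsupported element(s): %s",
                  paste(unique(el[!el %in% ELEMENT_WHITELIST]), collapse = ", ")))
  }
  hyb <- atom_hybridizations(mol)
  arom <- mol$atoms$aromatic
  nbrs <- atom_neighbors(mol)
  b <- mol$bonds
  n <- n_atoms(mol)
  dbl_o_count <- integer(n)   # number of =O neighbors
  for (r in seq_len(nrow(b))) {
    if (b$order[r] == 2L) {
      if (el[b$j[r]] == "O") dbl_o_count[b$i[r]] <- dbl_o_count[b$i[r]] + 1L
      if (el[b$i[r]] == "O") dbl_o_count[b$j[r]] <- dbl_o_count[b$j[r]] + 1L
    }
  }
  types <- character(n)
  for (a in seq_len(n)) {
    e <- el[a]
    types[a] <- switch(
      e,
      C = if (arom[a]) "C.ar" else c("C.1", "C.2", "C.3")[hyb[a]],
      N = {
        if (arom[a]) "N.ar"
        else if (mol$atoms$charge[a] > 0 && hyb[a] == 3L) "N.4"
        else if (hyb[a] == 3L &&
                 any(vapply(nbrs[[a]], function(x) el[x] == "C" && dbl_o_count[x] > 0,
                            logical(1)))) "N.am"
        else c("N.1", "N.2", "N.3")[hyb[a]]
      },
      O = {
        # both oxygens of a carboxyl(ate) group share one type
        carboxyl <- FALSE
        if (length(nbrs[[a]]) == 1L && el[nbrs[[a]]] == "C" &&
            dbl_o_count[nbrs[[a]]] > 0) {
          c_nbr <- nbrs[[a]]
          term_o <- sum(vapply(nbrs[[c_nbr]], function(x)
            el[x] == "O" && length(nbrs[[x]]) == 1L, logical(1)))
          carboxyl <- term_o >= 2L
        }
        if (carboxyl) "O.co2" else if (hyb[a] <= 2L && !arom[a]) "O.2" else "O.3"
      },
      S = {
        if (dbl_o_count[a] >= 2L) "S.o2"
        else if (dbl_o_count[a] == 1L) "S.o"
        else if (hyb[a] <= 2L && !arom[a]) "S.2" else "S.3"
      },
      P = "P.3",
      F = "F", Cl = "Cl", Br = "Br", I = "I",
      B = "B.3", Si = "Si.3"
    )
  }
  types
}

#' Sybyl-style type of a single atom
#'
#' @param mol A `som_mol`.
#' @param atom_index 1-based heavy-atom index.
#' @return One type code from [sybyl_atom_types()].
#' @export
sybyl_atom_type <- function(mol, atom_index) {
  stopifnot(atom_index >= 1, atom_index <= n_atoms(mol))
  sybyl_types(mol)[atom_index]
}
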