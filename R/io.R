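# Structure and annotation input/output.
#
# Structures come in as SDF (V2000) or SMILES; parsing is delegated to
# ChemmineR (SDF connection tables) and ChemmineOB/OpenBabel (SMILES ->
# kekulized SDF). Aromaticity of kekulized input is perceived with
# ChemmineR's ring detection. Annotations are a CSV table
# (mol_id, atom_index, is_som) or an SDF property "SOM_INDICES".

# Number of atoms declared on the counts line of a molfile record.
molfile_atom_count <- function(lines) {
  suppressWarnings(as.integer(substr(lines[4], 1, 3)))
}

# Single-heavy-atom records have no bond block and trip up the connection
# table reader, so they are built directly from the molfile atom line.
single_atom_mol <- function(lines, mol_id) {
  element <- trimws(substr(lines[5], 32, 34))
  chg <- 0L
  chg_line <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_line) > 0) {
    chg <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", chg_line[1])),
                               "\\s+")[[1]][2])
  }
  som_mol(mol_id, element, tibble(i = integer(), j = integer(), order = integer()),
          charges = chg)
}

# Convert one ChemmineR SDF object into a som_mol (no annotations yet).
# Explicit hydrogens are stripped; their count is re-derived implicitly.
sdf_to_mol <- function(sdf, mol_id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  n <- length(elements)
  charges <- integer(n)
  # ChemmineR stores M CHG values in atom block column 5 ("charge") when
  # present; fall back to 0.
  if (ncol(ab) >= 5) {
    ch <- ab[, 5]
    if (is.numeric(ch)) charges <- as.integer(ch)
  }
  bb <- if (is.null(bb)) NULL else as.matrix(bb)
  bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
    tibble(i = integer(), j = integer(), order = integer())
  } else {
    bb <- matrix(as.numeric(bb), ncol = ncol(bb))
    tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
           order = as.integer(bb[, 3]))
  }
  # aromatic perception on the kekulized table (covers order-4 input too)
  arom_atoms <- rep(FALSE, n)
  ring_info <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (!is.null(ring_info) && length(ring_info$RINGS) > 0) {
    for (k in seq_along(ring_info$RINGS)) {
      if (isTRUE(ring_info$AROMATIC[[k]])) {
        idx <- as.integer(gsub("^.*_", "", ring_info$RINGS[[k]]))
        arom_atoms[idx] <- TRUE
      }
    }
  }
  if (nrow(bonds) > 0) {
    bonds$aromatic <- arom_atoms[bonds$i] & arom_atoms[bonds$j] | bonds$order == 4L
  }
  keep <- which(elements != "H")
  if (length(keep) < n) {
    remap <- match(seq_len(n), keep)
    bonds <- bonds[bonds$i %in% keep & bonds$j %in% keep, ]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    elements <- elements[keep]; charges <- charges[keep]
    arom_atoms <- arom_atoms[keep]
  }
  som_mol(mol_id, elements, bonds, charges = charges, aromatic = arom_atoms)
}

#' Parse a SMILES string into an annotated molecule
#'
#' The SMILES is converted to a kekulized connection table with OpenBabel and
#' parsed into the package's graph container. Stereochemical information is
#' discarded (the container is purely topological).
#'
#' @param smiles A single SMILES string.
#' @param mol_id Identifier for the molecule (default `"mol"`).
#' @param som Optional integer vector of SoM atom indices (1-based, in the
#'   SMILES heavy-atom order).
#' @return A `som_mol`.
#' @export
#' @examples
#' \dontrun{
#' parse_smiles("c1ccccc1C", "toluene")
#' }
parse_smiles <- function(smiles, mol_id = "mol", som = NULL) {
  stopifnot(length(smiles) == 1)
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\t", mol_id, "\n"))
  lines <- strsplit(sdf_txt, "\n")[[1]]
  mol <- if (isTRUE(molfile_atom_count(lines) == 1L)) {
    single_atom_mol(lines, mol_id)
  } else {
    sdfset <- suppressWarnings(
      ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdf_txt)))
    )
    sdf_to_mol(sdfset[[1]], mol_id)
  }
  if (!is.null(som)) {
    som <- as.integer(som)
    if (any(som < 1 | som > n_atoms(mol))) {
      abort(sprintf("SoM atom index out of range for molecule '%s'", mol_id))
    }
    mol$som[som] <- TRUE
  }
  mol
}

#' Load an annotated molecule library from files
#'
#' Reads structures (SDF V2000 or a SMILES file with one
#' `SMILES<whitespace>id` record per line) and SoM annotations (CSV with
#' header `mol_id,atom_index,is_som`, `atom_index` 1-based; or, for SDF
#' input, a per-record `SOM_INDICES` property with space-separated indices).
#' Structures that fail to parse are skipped with a warning; annotations
#' referencing unknown molecules or out-of-range atoms raise an error.
#'
#' @param structures_path Path to an SDF or SMILES file.
#' @param annotations_path Optional path to the annotation CSV.
#' @param format `"auto"` (by extension), `"sdf"` or `"smiles"`.
#' @return A library tibble (see [som_library()]); flags not mentioned in the
#'   annotations are `FALSE`.
#' @export
read_som_library <- function(structures_path, annotations_path = NULL,
                             format = c("auto", "sdf", "smiles")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(sdf|mol)$", structures_path, ignore.case = TRUE))
      "sdf" else "smiles"
  }
  mols <- list()
  if (format == "sdf") {
    sdfstr <- suppressWarnings(ChemmineR::read.SDFstr(structures_path))
    record_lines <- as(sdfstr, "list")
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(sdfstr))
    ids <- ChemmineR::sdfid(sdfset)
    ids[is.na(ids) | ids == ""] <- paste0("mol", which(is.na(ids) | ids == ""))
    for (k in seq_along(sdfset)) {
      mol <- tryCatch({
        if (isTRUE(molfile_atom_count(record_lines[[k]]) == 1L)) {
          single_atom_mol(record_lines[[k]], ids[k])
        } else {
          sdf_to_mol(sdfset[[k]], ids[k])
        }
      }, error = function(e) {
        warn(sprintf("skipping unparsable record %d (%s): %s", k, ids[k],
                     conditionMessage(e)))
        NULL
      })
      if (is.null(mol)) next
      db <- ChemmineR::datablock(sdfset[[k]])
      if ("SOM_INDICES" %in% names(db) && nzchar(db[["SOM_INDICES"]])) {
        idx <- as.integer(strsplit(trimws(db[["SOM_INDICES"]]), "\\s+")[[1]])
        if (any(idx < 1 | idx > n_atoms(mol)))
          abort(sprintf("SOM_INDICES out of range for '%s'", ids[k]))
        mol$som[idx] <- TRUE
      }
      mols[[length(mols) + 1]] <- mol
    }
  } else {
    lines <- readLines(structures_path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (k in seq_along(lines)) {
      parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      id <- if (length(parts) >= 2) parts[2] else paste0("mol", k)
      mol <- tryCatch(parse_smiles(parts[1], id), error = function(e) {
        warn(sprintf("skipping unparsable SMILES line %d: %s", k,
                     conditionMessage(e)))
        NULL
      })
      if (!is.null(mol)) mols[[length(mols) + 1]] <- mol
    }
  }
  lib <- som_library(mols)
  if (!is.null(annotations_path)) {
    ann <- read.csv(annotations_path, stringsAsFactors = FALSE)
    stopifnot(all(c("mol_id", "atom_index", "is_som") %in% names(ann)))
    ann <- ann[as.logical(ann$is_som), , drop = FALSE]
    for (r in seq_len(nrow(ann))) {
      pos <- match(as.character(ann$mol_id[r]), lib$mol_id)
      if (is.na(pos)) abort(sprintf("annotation references unknown mol_id '%s'",
                                    ann$mol_id[r]))
      idx <- as.integer(ann$atom_index[r])
      if (idx < 1 || idx > n_atoms(lib$mol[[pos]]))
        abort(sprintf("annotation atom index %d out of range for '%s'",
                      idx, ann$mol_id[r]))
      lib$mol[[pos]]$som[idx] <- TRUE
    }
    lib$n_som <- map_int(lib$mol, ~ sum(.x$som))
  }
  lib
}

# Render one molecule as a V2000 molfile block (kekulized orders, M CHG).
mol_to_molfile <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  header <- sprintf("%s\n  somal 2D\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    mol$mol_id, n, nb)
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   mol$atoms$element)
  bonds <- if (nb > 0)
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$j, mol$bonds$order)
  else character()
  chg <- which(mol$atoms$charge != 0)
  chg_lines <- if (length(chg) > 0)
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf(" %3d %3d", chg, mol$atoms$charge[chg]), collapse = ""))
  else character()
  paste(c(header, atoms, bonds, chg_lines, "M  END"), collapse = "\n")
}

#' Write a curated library as SDF with SoM annotations
#'
#' Each record carries a `SOM_INDICES` property (space-separated 1-based
#' indices of flagged atoms) and a `PROVENANCE` property listing the source
#' ids merged into the record.
#'
#' @param library A library tibble.
#' @param path Output SDF path.
#' @return The path, invisibly.
#' @export
write_som_sdf <- function(library, path) {
  blocks <- map_chr(library$mol, function(m) {
    som_idx <- which(m$som)
    paste0(mol_to_molfile(m), "\n",
           ">  <SOM_INDICES>\n", paste(som_idx, collapse = " "), "\n\n",
           ">  <PROVENANCE>\n", paste(m$provenance, collapse = " "), "\n\n",
           "$$$$")
  })
  writeLines(blocks, path)
  invisible(path)
}

#' Standard InChI string of a molecule
#'
#' Generated with OpenBabel from the kekulized connection table. Used to
#' detect duplicate structures during curation.
#'
#' @param mol A `som_mol`.
#' @return The InChI string, or `NA` if generation fails.
#' @export
mol_inchi <- function(mol) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "INCHI",
                              paste0(mol_to_molfile(mol), "\n$$$$\n")),
    error = function(e) NA_character_
  )
  if (is.na(out) || !nzchar(trimws(out))) return(NA_character_)
  trimws(strsplit(out, "\n")[[1]][1])
}
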