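# Small reference molecules built in code, shared across test files.

mol_benzene <- function(som = NULL) parse_smiles("c1ccccc1", "benzene", som = som)
mol_para_xylene <- function(som = NULL) parse_smiles("Cc1ccc(C)cc1", "para_xylene", som = som)
mol_neopentane <- function() parse_smiles("CC(C)(C)C", "neopentane")
mol_pentane <- function() parse_smiles("CCCCC", "pentane")
mol_ethanol <- function(som = NULL) parse_smiles("CCO", "ethanol", som = som)
mol_anisole <- function() parse_smiles("COc1ccccc1", "anisole")

# A small featurized, deduplicated atom table; cached per session.
small_atom_table <- local({
  cache <- NULL
  function(n_mol = 30, seed = 5, depth = 5) {
    key <- paste(n_mol, seed, depth)
    if (!is.null(cache) && cache$key == key) return(cache$at)
    at <- deduplicate_atoms(
      featurize_library(generate_library(n_mol, seed = seed),
                        descriptor_config(depth = depth)))
    cache <<- list(key = key, at = at)
    at
  }
})

# Permute the atoms of a molecule with a fixed permutation (test helper for
# invariance properties): returns the permuted molecule and the permutation
# used (new order = old[perm]).
permuted_copy <- function(mol, seed = 1) {
  withr::local_seed(seed)
  perm <- sample(n_atoms(mol))
  list(mol = somal:::permute_mol(mol, perm), perm = perm)
}
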