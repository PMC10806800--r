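# Curation pipeline: parsing, annotation mapping, standardization,
# eligibility filtering, duplicate merging, symmetry closure.

test_that("annotations map onto parsed structures and out-of-range indices fail", {
  eth <- mol_ethanol(som = 3)
  expect_equal(eth$som, c(FALSE, FALSE, TRUE))
  expect_error(parse_smiles("CCO", "m", som = 9), "out of range")

  # CSV annotation round trip through files
  smi <- tempfile(fileext = ".smi")
  csv <- tempfile(fileext = ".csv")
  writeLines(c("CCO mol1", "c1ccccc1 mol2"), smi)
  write.csv(data.frame(mol_id = "mol1", atom_index = 3, is_som = TRUE),
            csv, row.names = FALSE)
  lib <- read_som_library(smi, csv)
  expect_equal(nrow(lib), 2)
  expect_equal(lib$n_som, c(1L, 0L))
  write.csv(data.frame(mol_id = "mol9", atom_index = 1, is_som = TRUE),
            csv, row.names = FALSE)
  expect_error(read_som_library(smi, csv), "unknown mol_id")
})

test_that("SDF round trip preserves structure and SoM indices", {
  lib <- generate_library(5, seed = 21)
  path <- tempfile(fileext = ".sdf")
  write_som_sdf(lib, path)
  back <- read_som_library(path)
  expect_equal(back$mol_id, lib$mol_id)
  expect_equal(back$n_atoms, lib$n_atoms)
  expect_equal(back$n_som, lib$n_som)
  for (k in seq_len(nrow(lib))) {
    expect_equal(mol_inchi(back$mol[[k]]), mol_inchi(lib$mol[[k]]))
  }
})

test_that("standardization strips salts, remaps SoM indices, and is idempotent", {
  # SoM on the kept component survives salt stripping (flag follows the O)
  m <- parse_smiles("CCO.[Na+]", "salted", som = 3)
  std <- standardize_mol(m)
  expect_equal(n_atoms(std), 3)
  expect_equal(sum(std$som), 1)
  expect_equal(std$atoms$element[std$som], "O")
  # SoM on the removed component is an error, not silent loss
  m2 <- parse_smiles("CCO.[Na+]", "salted2", som = 4)
  expect_error(standardize_mol(m2), "salt")
  # stereo input parses to the same graph as its flat form
  s1 <- standardize_mol(parse_smiles("C[C@H](N)O", "stereo"))
  s2 <- standardize_mol(parse_smiles("CC(N)O", "flat"))
  expect_true(somal:::identical_canonical(s1, s2))
  # idempotence
  std2 <- standardize_mol(std)
  expect_equal(std2$atoms, std$atoms)
  expect_equal(std2$bonds, std$bonds)
  expect_equal(std2$som, std$som)
})

test_that("eligibility rules reject low-MW, off-whitelist and unannotated molecules", {
  expect_equal(filter_eligible(mol_ethanol(som = 3))$rule, "molecular_weight")
  se <- parse_smiles("C[Se]c1ccc(CCNC(C)C)cc1", "selenide", som = 1)
  expect_equal(filter_eligible(se)$rule, "element_whitelist")
  no_som <- parse_smiles("COc1ccc(CCN)cc1", "clean")
  expect_equal(filter_eligible(no_som)$rule, "has_som")
  ok <- parse_smiles("COc1ccc(CCNC(C)C)cc1", "druglike", som = 1)
  expect_true(filter_eligible(ok)$accepted)
  # MW bounds are inclusive
  expect_true(mol_weight(ok) >= 100 && mol_weight(ok) <= 1000)
})

test_that("duplicate merge unions annotations across symmetry-equivalent atoms", {
  # two para-xylene copies annotated on the two different (equivalent)
  # methyl carbons collapse to one record with both methyls flagged
  a <- standardize_mol(mol_para_xylene(som = 1))
  b <- standardize_mol(mol_para_xylene(som = 6))
  merged <- merge_duplicates(list(a, b))
  expect_length(merged, 1)
  m <- merged[[1]]
  methyls <- which(m$atoms$n_h == 3)
  expect_equal(which(m$som), methyls)
  expect_setequal(m$provenance, c("para_xylene", "para_xylene"))
  # distinct molecules stay distinct
  two <- merge_duplicates(list(standardize_mol(mol_anisole()),
                               standardize_mol(mol_ethanol(som = 1))))
  expect_length(two, 2)
})

test_that("symmetry closure expands one flagged benzene carbon to all six", {
  m <- close_som_symmetry(mol_benzene(som = 2))
  expect_equal(sum(m$som), 6)
  # and neopentane methyls form one class of four
  cls <- atom_symmetry_classes(mol_neopentane())
  expect_equal(sort(tabulate(cls)), c(1, 4))
})

test_that("curation is idempotent, count-conserving and order-independent", {
  mols <- list(
    parse_smiles("CCOc1ccccc1", "a1", som = 2),
    parse_smiles("CCOc1ccccc1", "a2", som = 2),
    parse_smiles("CCO.[Na+]", "tiny"),
    parse_smiles("CC(=O)Oc1ccccc1C(=O)O", "aspirin", som = 1)
  )
  cur <- curate_library(som_library(mols))
  rep <- curation_report(cur)
  expect_equal(rep$n_output,
               rep$n_input - rep$n_rejected - rep$n_merged_duplicates)
  expect_equal(rep$n_output, 2L)
  # idempotent
  cur2 <- curate_library(cur)
  expect_equal(curation_report(cur2)$n_rejected, 0L)
  expect_equal(cur2$mol_id, cur$mol_id)
  for (k in seq_len(nrow(cur))) {
    expect_true(somal:::identical_canonical(cur2$mol[[k]], cur$mol[[k]]))
    expect_equal(cur2$mol[[k]]$som, cur$mol[[k]]$som)
  }
  # order independence (up to provenance)
  cur_rev <- curate_library(som_library(rev(mols)))
  expect_equal(cur_rev$mol_id %in% cur$mol_id |
                 cur_rev$mol_id %in% c("a2"), rep(TRUE, nrow(cur_rev)))
  expect_equal(sort(purrr::map_chr(cur_rev$mol, mol_inchi)),
               sort(purrr::map_chr(cur$mol, mol_inchi)))
  # flags constant on every automorphism class of every output molecule
  for (m in cur$mol) {
    cls <- atom_symmetry_classes(m)
    for (cl in unique(cls)) {
      expect_length(unique(m$som[cls == cl]), 1)
    }
  }
})
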