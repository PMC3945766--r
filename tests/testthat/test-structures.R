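test_that("standardization strips salts, neutralizes charges, and counts heavy atoms", {
  m <- standardize_molecules(c("CCO", "CCO.[Na+].[Cl-]", "CC(=O)[O-]"))
  expect_equal(m$heavy_atoms, c(3L, 3L, 4L))
  # the salt form collapses onto plain ethanol
  expect_equal(m$canonical_smiles[2], m$canonical_smiles[1])
  # deprotonated acetate is rebalanced to the neutral acid
  expect_equal(m$canonical_smiles[3],
               standardize("CC(=O)O")$canonical_smiles)
  # a quaternary ammonium has no proton to remove and keeps its charge
  q <- standardize("C[N+](C)(C)C.[Cl-]")
  expect_match(q$canonical_smiles, "N\\+")
})

test_that("unparsable SMILES are rejected per record, not per batch", {
  m <- standardize_molecules(c("CCO", "C1CC", "c1ccccc1"))
  expect_equal(is.na(m$canonical_smiles), c(FALSE, TRUE, FALSE))
  expect_match(m$error[2], "unparsable")
  expect_equal(attr(m, "n_failed"), 1L)
  expect_error(standardize("C1CC"), "unparsable")
  expect_equal(nrow(valid_molecules(m)), 2L)
})

test_that("standardization is idempotent and yields one component", {
  mol <- valid_molecules(shared_molecules())
  expect_false(any(grepl(".", mol$canonical_smiles, fixed = TRUE)))
  again <- standardize_molecules(
    tibble::tibble(compound_id = mol$compound_id,
                   smiles = mol$canonical_smiles))
  expect_equal(again$canonical_smiles, mol$canonical_smiles)
  expect_equal(again$heavy_atoms, mol$heavy_atoms)
  expect_true(all(mol$heavy_atoms >= 1))
})

test_that("largest-component ties break by smallest canonical SMILES", {
  # two disconnected organic components of equal size
  m <- standardize("CCO.CCN")
  expect_equal(m$canonical_smiles, "CCN")
  expect_equal(m$heavy_atoms, 3L)
})

test_that("fragment heavy-atom counting honours the attachment contract", {
  expect_equal(heavy_atoms(c("[*]C", "[*]c1ccccc1", H_FRAGMENT)),
               c(1L, 6L, 0L))
  expect_error(heavy_atoms("[*]C[*]"), "attachment")
})

test_that("heavy atoms are additive under fragment reattachment", {
  mol <- valid_molecules(shared_molecules())
  cuts <- enumerate_cuts(mol)
  expect_gt(nrow(cuts), 0)
  expect_equal(heavy_atoms(cuts$core) + heavy_atoms(cuts$fragment),
               mol$heavy_atoms[match(cuts$compound_id, mol$compound_id)])
})

test_that("SMILES files parse as (smiles, identifier) records", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1\tmol2", "CCN"), f)
  tab <- read_smiles_file(f)
  expect_equal(tab$smiles, c("CCO", "c1ccccc1", "CCN"))
  expect_equal(tab$compound_id[1:2], c("mol1", "mol2"))
})
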