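test_that("classic bond classes are recognized on reference molecules", {
  # acetanilide: the C(=O)-N bond is an amide cut
  b <- identify_retro_bonds("CC(=O)Nc1ccccc1")
  expect_equal(nrow(b), 1L)
  expect_match(b$rule_ids, "amide")

  # methyl benzoate: the C(=O)-O bond is an ester cut (and the O-CH3 bond
  # is excluded from the ether class by the acyl guard)
  b <- identify_retro_bonds("COC(=O)c1ccccc1")
  expect_equal(nrow(b), 1L)
  expect_match(b$rule_ids, "ester")

  # biphenyl: the biaryl single bond
  b <- identify_retro_bonds("c1ccc(-c2ccccc2)cc1")
  expect_equal(nrow(b), 1L)
  expect_match(b$rule_ids, "aromatic_c_aromatic_c")

  # ring bonds never qualify, nor do plain alkane bonds
  expect_equal(nrow(identify_retro_bonds("C1CCCCC1")), 0L)
  expect_equal(nrow(identify_retro_bonds("CC")), 0L)
})

test_that("retro cuts mirror standard cuts restricted to rule bonds", {
  cuts <- enumerate_retro_cuts("CC(=O)Nc1ccccc1")
  expect_equal(nrow(cuts), 2L)  # one bond, both orientations
  expect_setequal(cuts$core, c("*C(C)=O", "*Nc1ccccc1"))
  expect_equal(nrow(enumerate_retro_cuts("CC")), 0L)
  # no hydrogen expansion in retro mode
  expect_false(any(cuts$fragment == H_FRAGMENT))
})

test_that("single-bond retro cuts are a subset of the standard cut set", {
  mol <- valid_molecules(shared_molecules())
  std <- enumerate_cuts(mol, hydrogen = FALSE)
  ret <- enumerate_retro_cuts(mol)
  key <- function(d) paste(d$compound_id, d$core, d$fragment)
  expect_true(all(key(ret) %in% key(std)))
})

test_that("retro cuts reassemble and their rules re-match the parent", {
  mol <- valid_molecules(shared_molecules())
  ret <- enumerate_retro_cuts(mol)
  expect_gt(nrow(ret), 0)
  audit <- audit_retro_cuts(ret)
  expect_true(all(audit$rule_rematches))
  cut_audit <- audit_cuts(ret, mol)
  expect_true(all(cut_audit$conserves))
  expect_true(all(cut_audit$reassembles))
})

test_that("homologous naphthalenyl amides form a size-legal RECAP-MMP", {
  mol <- standardize_molecules(tibble::tibble(
    compound_id = c("acet", "prop"),
    smiles = c("CC(=O)Nc1ccc2ccccc2c1", "CCC(=O)Nc1ccc2ccccc2c1")))
  ret <- enumerate_retro_cuts(mol)
  shared <- "*Nc1ccc2ccccc2c1"
  expect_true(all(c("acet", "prop") %in%
                    ret$compound_id[ret$core == shared]))
  expect_equal(unique(ret$core_heavy[ret$core == shared]), 11L)
  mm <- assemble_mmps(build_fragment_index(ret))
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$core, shared)
  expect_setequal(c(mm$frag_a_heavy, mm$frag_b_heavy), c(3L, 4L))
})

test_that("a malformed SMARTS in the rule file fails at load time", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rule_id\tsmarts\tenabled", "bad\t[[C:1]-[N:2]\tTRUE"), f)
  expect_error(read_retro_rules(f), "malformed SMARTS")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rule_id\tsmarts\tenabled", "bad\t[C:1]-[N:3]\tTRUE"), f2)
  expect_error(read_retro_rules(f2), "map")
})

test_that("the olefin rule is off by default but cuts double bonds when enabled", {
  sty <- "C=Cc1ccccc1"
  expect_equal(nrow(enumerate_retro_cuts(sty)), 0L)
  rules <- default_retro_rules()
  rules$enabled[rules$rule_id == "olefin"] <- TRUE
  cuts <- enumerate_retro_cuts(sty, rules)
  expect_equal(nrow(cuts), 2L)
  # reassembly restores the double bond
  audit <- audit_cuts(cuts, tibble::tibble(
    compound_id = sty, canonical_smiles = standardize(sty)$canonical_smiles,
    heavy_atoms = 8L, error = ""))
  expect_true(all(audit$reassembles))
  expect_true(all(audit$conserves))
})
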