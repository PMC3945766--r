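test_that("single cuts enumerate every exocyclic single bond in both orientations", {
  eb <- enumerate_single_cuts("CCc1ccccc1")
  expect_equal(nrow(eb), 4L)  # 2 cleavable bonds x 2 orientations
  expect_true(any(eb$core == "*Cc1ccccc1" & eb$fragment == "*C"))
  expect_true(any(eb$core == "*C" & eb$fragment == "*Cc1ccccc1"))
  expect_equal(nrow(enumerate_single_cuts("c1ccccc1")), 0L)  # ring bonds only
  expect_equal(nrow(enumerate_single_cuts("C")), 0L)         # no heavy-heavy bond
  # double bonds are never cut by standard fragmentation
  expect_equal(nrow(enumerate_single_cuts("C=C")), 0L)
})

test_that("hydrogen expansion deduplicates symmetry-equivalent positions", {
  bz <- hydrogen_expansion("c1ccccc1")
  expect_equal(nrow(bz), 1L)
  expect_equal(bz$core, "*c1ccccc1")
  expect_equal(bz$fragment, H_FRAGMENT)
  expect_equal(bz$frag_heavy, 0L)

  tol <- hydrogen_expansion("Cc1ccccc1")
  expect_true(any(tol$core == "*Cc1ccccc1"))
  expect_equal(nrow(tol), 4L)  # methyl + ortho/meta/para ring positions

  # no hydrogens on heavy atoms, no expansion
  expect_equal(nrow(hydrogen_expansion("FC(F)(F)C(F)(F)F")), 0L)
})

test_that("every cut conserves atoms and reassembles to its parent", {
  mol <- valid_molecules(shared_molecules())
  cuts <- enumerate_cuts(mol, hydrogen = TRUE)
  audit <- audit_cuts(cuts, mol)
  expect_gt(nrow(audit), 0)
  expect_true(all(audit$conserves))
  expect_true(all(audit$reassembles))
})

test_that("the fragment index is keyed by core and deduplicated", {
  mol <- standardize_molecules(
    tibble::tibble(compound_id = c("tol", "eb"),
                   smiles = c("Cc1ccccc1", "CCc1ccccc1")))
  idx <- build_fragment_index(enumerate_cuts(mol))
  phenyl <- idx[idx$core == "*c1ccccc1", ]
  expect_equal(nrow(phenyl), 2L)
  expect_setequal(phenyl$fragment, c("*C", "*CC"))

  # singleton input: every key holds exactly one entry
  idx1 <- build_fragment_index(enumerate_cuts(mol[1, ]))
  expect_true(all(table(idx1$core) == 1))

  # empty input: empty index
  idx0 <- build_fragment_index(enumerate_cuts(mol[0, ]))
  expect_equal(nrow(idx0), 0L)

  # duplicated cut rows collapse to unique triples
  cuts <- enumerate_cuts(mol)
  expect_equal(build_fragment_index(rbind(cuts, cuts)), idx)
})

test_that("index sharing agrees with brute-force cut comparison", {
  mol <- rand_target_molecules(301)
  cuts <- enumerate_cuts(mol)
  idx <- build_fragment_index(cuts)
  # two molecules share an index key iff their cut lists share a core
  share_idx <- function(a, b) {
    any(idx$core[idx$compound_id == a] %in% idx$core[idx$compound_id == b])
  }
  share_brute <- function(a, b) {
    any(cuts$core[cuts$compound_id == a] %in% cuts$core[cuts$compound_id == b])
  }
  ids <- mol$compound_id
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      expect_equal(share_idx(ids[i], ids[j]), share_brute(ids[i], ids[j]))
    }
  }
})
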