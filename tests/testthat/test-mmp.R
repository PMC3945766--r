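test_that("transformation size rules hold at their boundaries", {
  expect_true(apply_size_rules(26, 13, 5))    # all three limits touched
  expect_false(apply_size_rules(20, 13, 4))   # size difference 9 > 8
  expect_false(apply_size_rules(10, 6, 5))    # core smaller than 2 x 6
  expect_false(apply_size_rules(28, 14, 6))   # fragment above 13
  expect_true(apply_size_rules(1, 0, 0))      # hydrogen vs hydrogen-sized
  # vectorized
  expect_equal(apply_size_rules(c(26, 20, 10), c(13, 13, 6), c(5, 4, 5)),
               c(TRUE, FALSE, FALSE))
  # parameters are honoured
  expect_true(apply_size_rules(10, 6, 5, core_multiple = 1))
})

test_that("toluene/ethylbenzene assembles one canonical MMP over the largest context", {
  mol <- standardize_molecules(
    tibble::tibble(compound_id = c("eb", "tol"),
                   smiles = c("CCc1ccccc1", "Cc1ccccc1")))
  idx <- build_fragment_index(enumerate_cuts(mol))
  mm <- assemble_mmps(idx)
  expect_equal(nrow(mm), 1L)
  # H -> methyl at the 7-atom benzyl core beats methyl -> ethyl at phenyl:
  # its larger fragment (1 atom) is smaller than the alternative's (2)
  expect_equal(mm$core, "*Cc1ccccc1")
  expect_equal(mm$core_heavy, 7L)
  expect_equal(mm$transformation, paste0("*C>>", H_FRAGMENT))
  # the exhaustive listing retains the phenyl-core alternative
  ex <- assemble_mmps(idx, exhaustive = TRUE)
  expect_equal(nrow(ex), 2L)
  expect_setequal(ex$core, c("*Cc1ccccc1", "*c1ccccc1"))
})

test_that("core keys with one entry or one compound yield no MMP", {
  mol <- standardize_molecules(
    tibble::tibble(compound_id = "tol", smiles = "Cc1ccccc1"))
  idx <- build_fragment_index(enumerate_cuts(mol))
  expect_equal(nrow(assemble_mmps(idx)), 0L)
})

test_that("assembly is invariant under input order", {
  mol <- valid_molecules(shared_molecules())
  cuts <- enumerate_cuts(mol)
  idx <- build_fragment_index(cuts)
  rev_idx <- build_fragment_index(cuts[rev(seq_len(nrow(cuts))), ])
  expect_equal(assemble_mmps(idx), assemble_mmps(rev_idx))
})

test_that("canonical selection ordering follows (max fragment, total, core)", {
  cand <- tibble::tibble(
    cpd_a = "A", cpd_b = "B",
    core = c("*CCZ", "*CCA", "*D"),
    core_heavy = c(7L, 7L, 6L),
    frag_a = c("*x", "*y", "*z"), frag_b = c("*p", "*q", "*r"),
    frag_a_heavy = c(1L, 1L, 1L), frag_b_heavy = c(0L, 0L, 2L),
    transformation = c("t1", "t2", "t3")
  )
  pick <- select_canonical(cand)
  expect_equal(nrow(pick), 1L)
  # max fragment 1 beats 2; tie on sizes resolved by smaller core string
  expect_equal(pick$core, "*CCA")
  expect_equal(select_canonical(cand[3, ]), cand[3, ])
})

test_that("cliff detection thresholds and orientation behave as specified", {
  mm <- tibble::tibble(cpd_a = c("A", "C", "E"), cpd_b = c("B", "D", "F"),
                       core = "*X", core_heavy = 10L,
                       frag_a = "*C", frag_b = "*N",
                       frag_a_heavy = 1L, frag_b_heavy = 1L,
                       transformation = "*C>>*N")
  ts <- tibble::tibble(compound_id = c("A", "B", "C", "D", "E", "F"),
                       pPotency = c(7.2, 5.0, 5.0, 6.5, 6.0, 6.0))
  cl2 <- detect_cliffs(mm, ts, threshold_oom = 2)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$delta, 2.2)
  expect_equal(cl2$cpd_low, "B")   # oriented less -> more potent
  expect_equal(cl2$cpd_high, "A")
  cl1 <- detect_cliffs(mm, ts, threshold_oom = 1)
  expect_setequal(cl1$cpd_a, c("A", "C"))  # 5.0 vs 6.5 enters at 1 OoM
  # equal potencies are never a cliff at any positive threshold
  expect_false("E" %in% cl1$cpd_a)
  expect_error(detect_cliffs(mm, ts[-1, ], threshold_oom = 2),
               "without potency")
})

test_that("cliffs nest across thresholds on the planted data", {
  res <- shared_pipeline()
  key <- function(d) paste(d$target_id, d$cpd_a, d$cpd_b)
  expect_true(all(key(res$cliffs[["2"]]) %in% key(res$cliffs[["1"]])))
  expect_lte(nrow(res$cliffs[["2"]]), nrow(res$cliffs[["1"]]))
})

test_that("every emitted MMP passes the independent size audit", {
  res <- shared_pipeline()
  expect_true(all(audit_size_rules(res$mmps)))
  expect_true(all(audit_size_rules(res$recap_mmps)))
})
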