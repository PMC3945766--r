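pairs_tbl <- function(a, b) {
  tibble::tibble(fragment = sprintf("*S%d", seq_along(a)),
                 cpd_a = sprintf("A%d", seq_along(a)),
                 cpd_b = sprintf("B%d", seq_along(a)),
                 pPot_a = a, pPot_b = b)
}

test_that("progression classes follow the Spearman hand calculations", {
  r <- classify_progression(pairs_tbl(c(5, 6, 7), c(6, 7, 8)))
  expect_equal(r$progression, "regular")
  expect_equal(r$rank_correlation, 1)

  r <- classify_progression(pairs_tbl(c(5, 6, 7, 8), c(5, 7, 6, 8)))
  expect_equal(r$progression, "approximate")
  expect_equal(r$rank_correlation, 0.8)

  r <- classify_progression(pairs_tbl(c(5, 6, 7), c(5, 7, 6)))
  expect_equal(r$progression, "none")
  expect_equal(r$rank_correlation, 0.5)

  expect_error(classify_progression(pairs_tbl(c(5, 6), c(5, 6))), "3 pairs")
})

test_that("a potency tie disqualifies the regular class", {
  r <- classify_progression(pairs_tbl(c(5, 6, 7), c(6, 6, 8)))
  expect_false(r$progression == "regular")
  # tie in the ordering series too
  r <- classify_progression(pairs_tbl(c(5, 5, 7), c(6, 7, 8)))
  expect_false(r$progression == "regular")
})

test_that("regular classification is symmetric in the two series", {
  p <- pairs_tbl(c(5, 6.2, 7.9), c(6.1, 7.4, 8.8))
  swapped <- p
  swapped$pPot_a <- p$pPot_b
  swapped$pPot_b <- p$pPot_a
  expect_equal(classify_progression(p)$progression,
               classify_progression(swapped)$progression)
})

test_that("analog series group substituted analogs under their shared core", {
  ts <- tibble::tibble(
    target_id = "T", measurement_kind = "Ki",
    compound_id = c("b1", "b2", "b3", "b4"),
    canonical_smiles = c("NC(=O)c1ccccc1", "NC(=O)c1ccc(F)cc1",
                         "NC(=O)c1ccc(Cl)cc1", "NC(=O)c1ccc(C)cc1"),
    pPotency = c(5, 6, 7, 8))
  ser <- extract_series(ts)
  core <- "*c1ccc(C(N)=O)cc1"
  benz <- ser[ser$core == core, ]
  expect_equal(nrow(benz), 4L)
  expect_setequal(benz$fragment, c(H_FRAGMENT, "*F", "*Cl", "*C"))
  # per-cut size rules hold for every member
  expect_true(all(ser$core_heavy >= 2 * ser$frag_heavy))
  expect_true(all(ser$frag_heavy <= 13))
})

test_that("matching requires three shared substituents and two log units of span", {
  mk <- function(core, frags, pots) {
    tibble::tibble(core = core, core_heavy = 10L, fragment = frags,
                   frag_heavy = 1L, compound_id = paste0(core, frags),
                   pPotency = pots)
  }
  # only two shared substituents: rejected
  s <- rbind(mk("*A", c("*x", "*y", "*z"), c(5, 6, 8)),
             mk("*B", c("*x", "*y", "*w"), c(5, 6, 8)))
  expect_equal(nrow(find_matching_series(s)), 0L)
  # three shared but span 1.5 in one series: rejected
  s <- rbind(mk("*A", c("*x", "*y", "*z"), c(5, 6, 8)),
             mk("*B", c("*x", "*y", "*z"), c(5, 5.7, 6.5)))
  expect_equal(nrow(find_matching_series(s)), 0L)
  # three shared, both spans >= 2: accepted
  s <- rbind(mk("*A", c("*x", "*y", "*z"), c(5, 6, 8)),
             mk("*B", c("*x", "*y", "*z"), c(6, 7.1, 9)))
  m <- find_matching_series(s)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_pairs, 3L)
  expect_equal(m$span_a, 3)
  expect_equal(m$span_b, 3)
  # span is computed over matched pairs only
  s2 <- rbind(s, mk("*A", "*only", 20))
  expect_equal(find_matching_series(s2)$span_a, 3)
})

test_that("the planted transfer series is regular and a derangement destroys it", {
  res <- shared_pipeline()
  m <- res$matching
  expect_gte(nrow(m), 1L)
  expect_true(all(m$progression == "regular"))
  expect_equal(m$rank_correlation, rep(1, nrow(m)))
  # nesting: regular subset of transfer subset of matching
  expect_lte(sum(m$progression == "regular"),
             sum(m$progression %in% c("regular", "approximate")))
  expect_lte(sum(m$progression %in% c("regular", "approximate")), nrow(m))

  p <- m$pairs[[1]]
  set.seed(7)
  repeat {  # a seeded derangement of one series' potencies
    perm <- sample(nrow(p))
    if (all(perm != seq_len(nrow(p)))) break
  }
  p$pPot_b <- p$pPot_b[perm]
  expect_false(classify_progression(p)$progression == "regular")
})
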