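test_that("fixture generation is deterministic for a given seed and plan", {
  a <- generate_fixture(fixture_plan(seed = 11, noise_sd = 0.2))
  b <- generate_fixture(fixture_plan(seed = 11, noise_sd = 0.2))
  expect_identical(a$compounds, b$compounds)
  expect_identical(a$activities, b$activities)
  c <- generate_fixture(fixture_plan(seed = 12, noise_sd = 0.2))
  expect_false(identical(a$activities$value_nM, c$activities$value_nM))
})

test_that("the combinatorial oracle counts pairs per core", {
  plan <- fixture_plan(seed = 1, targets = default_fixture_targets()[1],
                       decoys = FALSE)
  fx <- generate_fixture(plan)
  # 2 cores x 5 substituents
  expect_equal(nrow(fx$compounds), 10L)
  man <- fx$manifest$targets
  # all substituents are size-legal on both cores: C(5,2) pairs per core
  expect_equal(man$mmp_pairs, 2 * choose(5, 2))
  expect_equal(man$mmp_compounds, 10L)
})

test_that("substituent effect levels place exactly the spanning pairs on cliffs", {
  tgt <- fixture_target(
    "T-X", "Ki",
    cores = tibble::tibble(name = "phenyl", smiles = "[*]c1ccccc1",
                           heavy = 6, effect = 5),
    subs = tibble::tibble(name = c("H", "fluoro", "methyl"),
                          smiles = c(H_FRAGMENT, "[*]F", "[*]C"),
                          heavy = c(0, 1, 1), effect = c(0, 0, 2.5)))
  man <- fixture_manifest(fixture_plan(seed = 1, targets = list(tgt),
                                       decoys = FALSE))
  # pairs crossing the 2.5-unit gap are cliffs at 2 OoM; the tied pair is not
  expect_equal(man$targets$mmp_pairs, 3L)
  expect_equal(man$targets$cliff_pairs_2, 2L)
  expect_equal(man$targets$cliff_pairs_1, 2L)
})

test_that("invalid plans fail loudly at generation time", {
  bad_combo <- fixture_target(
    "T-B", "Ki",
    cores = tibble::tibble(name = "noattach", smiles = "c1ccccc1",
                           heavy = 6, effect = 5),
    subs = tibble::tibble(name = "methyl", smiles = "[*]C",
                          heavy = 1, effect = 0))
  expect_error(
    generate_fixture(fixture_plan(seed = 1, targets = list(bad_combo),
                                  decoys = FALSE)),
    "invalid scaffold/substituent")

  bad_heavy <- fixture_target(
    "T-B", "Ki",
    cores = tibble::tibble(name = "phenyl", smiles = "[*]c1ccccc1",
                           heavy = 7, effect = 5),
    subs = tibble::tibble(name = "methyl", smiles = "[*]C",
                          heavy = 1, effect = 0))
  expect_error(
    generate_fixture(fixture_plan(seed = 1, targets = list(bad_heavy),
                                  decoys = FALSE)),
    "heavy-atom")
})

test_that("activity tables use the curation dialect and decoys are planted", {
  fx <- shared_fixture()
  expect_true(all(c("compound_id", "target_id", "measurement_kind",
                    "relation", "value_nM", "confidence_score",
                    "relationship_type") %in% names(fx$activities)))
  expect_true(any(fx$activities$relation == ">"))
  expect_true(any(fx$activities$confidence_score != 9))
  expect_true(any(fx$activities$relationship_type != "D"))
  # potencies encode the additive model: pKi = 9 - log10(nM)
  one <- fx$activities[fx$activities$compound_id == "T-KIN1-phenyl-H", ]
  expect_equal(9 - log10(one$value_nM), 4.5)
})
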