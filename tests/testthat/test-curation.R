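make_record <- function(compound_id = "C1", target_id = "T1",
                        measurement_kind = "Ki", relation = "=",
                        value_nM = 50, confidence_score = 9,
                        relationship_type = "D") {
  tibble::tibble(compound_id = compound_id, target_id = target_id,
                 measurement_kind = measurement_kind, relation = relation,
                 value_nM = value_nM, confidence_score = confidence_score,
                 relationship_type = relationship_type)
}

test_that("high-confidence filter drops exactly the offending records", {
  recs <- dplyr::bind_rows(
    make_record(),                                   # retained
    make_record(relation = ">"),
    make_record(relation = "<"),
    make_record(relation = "~"),
    make_record(confidence_score = 8),
    make_record(relationship_type = "N"),
    make_record(measurement_kind = "EC50"),
    make_record(value_nM = NA),
    make_record(value_nM = -1)
  )
  kept <- filter_activity_records(recs)
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "drop_counts"),
               c(missing_value = 1L, relation = 3L, confidence = 1L,
                 relationship = 1L, kind = 1L, nonpositive = 1L))
  # idempotence: refiltering the retained set drops nothing
  again <- filter_activity_records(kept)
  expect_equal(nrow(again), nrow(kept))
  expect_true(all(attr(again, "drop_counts") == 0L))
})

test_that("replicate aggregation uses the geometric mean within one order of magnitude", {
  expect_equal(aggregate_potency(c(10, 100)), 7.5)
  expect_equal(aggregate_potency(c(100, 10)), 7.5)
  expect_true(is.na(aggregate_potency(c(1, 1000))))
  expect_equal(aggregate_potency(50), 9 - log10(50))
  # the window is inclusive: exactly a 10x spread still aggregates
  expect_equal(aggregate_potency(c(10, 100, 31.6227766)),
               9 - mean(log10(c(10, 100, 31.6227766))))
  expect_error(aggregate_potency(c(10, -1)), "positive")
})

test_that("aggregated potency always lies within the replicate range", {
  set.seed(42)
  for (i in 1:25) {
    vals <- 10^stats::runif(sample(2:5, 1), 0, 1) * 10^sample(0:3, 1)
    p <- aggregate_potency(vals)
    pr <- 9 - log10(vals)
    if (max(vals) / min(vals) <= 10) {
      expect_gte(p, min(pr))
      expect_lte(p, max(pr))
    } else {
      expect_true(is.na(p))
    }
  }
})

test_that("target sets separate targets and measurement kinds", {
  mols <- standardize_molecules(
    tibble::tibble(compound_id = c("C1", "C2", "C3"),
                   smiles = c("CCO", "CCN", "CCF")))
  recs <- dplyr::bind_rows(
    make_record("C1", "T1"), make_record("C2", "T1"),
    make_record("C3", "T2"),
    make_record("C1", "T1", measurement_kind = "IC50")
  )
  ts <- build_target_sets(filter_activity_records(recs), mols)
  key <- unique(paste(ts$target_id, ts$measurement_kind))
  expect_setequal(key, c("T1 Ki", "T2 Ki", "T1 IC50"))
  # Ki and IC50 never co-occur in one target set
  sets <- split_target_sets(ts)
  expect_true(all(vapply(sets, function(s) {
    length(unique(s$measurement_kind)) == 1
  }, TRUE)))
  # member count bounded by distinct (compound, target, kind) triples
  expect_lte(nrow(ts), 4L)
})

test_that("structural duplicates merge before replicate aggregation", {
  mols <- standardize_molecules(
    tibble::tibble(compound_id = c("A", "B"),
                   smiles = c("OCC", "CCO")))  # same structure, two ids
  recs <- dplyr::bind_rows(make_record("A", value_nM = 10),
                           make_record("B", value_nM = 20))
  ts <- build_target_sets(filter_activity_records(recs), mols)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$compound_id, "A")  # smallest identifier survives
  expect_equal(ts$pPotency, 9 - log10(sqrt(10 * 20)))
  expect_equal(round(ts$pPotency, 4), 7.8495)
  expect_equal(attr(ts, "n_duplicates_merged"), 1L)
})

test_that("records without a standardized structure are skipped, not fatal", {
  mols <- standardize_molecules(
    tibble::tibble(compound_id = c("C1", "C2"), smiles = c("CCO", "C1CC")))
  recs <- dplyr::bind_rows(make_record("C1"), make_record("C2"))
  ts <- build_target_sets(filter_activity_records(recs), mols)
  expect_equal(ts$compound_id, "C1")
  expect_equal(attr(ts, "n_no_structure"), 1L)
})
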