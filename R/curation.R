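# Activity-record curation: high-confidence filtering, replicate
# aggregation, and per-target / per-measurement-kind compound sets.

MEASUREMENT_KINDS <- c("Ki", "IC50")

#' Filter activity records to high-confidence data
#'
#' Retains records with an exact potency value (relation `"="`), the highest
#' target confidence score (9), a direct target relationship (type `"D"`),
#' a supported measurement kind (Ki or IC50), and a positive potency value.
#' Approximate measurements (`">"`, `"<"`, `"~"`) and inconclusive records
#' (missing value) are dropped. The operation is idempotent.
#'
#' @param records data frame with columns `compound_id`, `target_id`,
#'   `measurement_kind`, `relation`, `value_nM`, `confidence_score`,
#'   `relationship_type`.
#' @return the retained records, with a named integer attribute
#'   `drop_counts` giving the number dropped per reason
#'   (`missing_value`, `relation`, `confidence`, `relationship`, `kind`,
#'   `nonpositive`). A record failing several filters is counted under the
#'   first in that order.
#' @export
filter_activity_records <- function(records) {
  required <- c("compound_id", "target_id", "measurement_kind", "relation",
                "value_nM", "confidence_score", "relationship_type")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0) {
    stop("activity table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  val <- suppressWarnings(as.numeric(records$value_nM))

  reason <- rep(NA_character_, nrow(records))
  mark <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- mark(is.na(val), "missing_value")
  reason <- mark(records$relation != "=", "relation")
  reason <- mark(records$confidence_score != 9, "confidence")
  reason <- mark(records$relationship_type != "D", "relationship")
  reason <- mark(!records$measurement_kind %in% MEASUREMENT_KINDS, "kind")
  reason <- mark(val <= 0, "nonpositive")

  kept <- records[is.na(reason), , drop = FALSE]
  kept$value_nM <- val[is.na(reason)]
  labels <- c("missing_value", "relation", "confidence", "relationship",
              "kind", "nonpositive")
  counts <- vapply(labels, function(l) sum(reason == l, na.rm = TRUE), 1L)
  attr(kept, "drop_counts") <- counts
  kept
}

#' Aggregate replicate potency measurements
#'
#' For a compound measured several times against the same target, the final
#' potency annotation is the geometric mean of the nanomolar values, provided
#' all values fall within one order of magnitude (max/min <= 10, inclusive);
#' otherwise the compound is discarded and `NA` is returned as the discard
#' sentinel. The result is expressed as pPotency = 9 - log10(value in nM),
#' i.e. the negative decadic logarithm of the molar potency.
#'
#' @param values_nM numeric vector of positive potency values in nM.
#' @param oom_window inclusive replicate-spread bound on the nM scale
#'   (default 10 = one order of magnitude).
#' @return pPotency (dimensionless log unit), or `NA_real_` when the
#'   replicates violate the spread rule.
#' @export
#' @examples
#' \dontrun{
#' aggregate_potency(c(10, 100))   # 7.5
#' aggregate_potency(c(1, 1000))   # NA (discarded)
#' }
aggregate_potency <- function(values_nM, oom_window = 10) {
  stopifnot(length(values_nM) >= 1, is.numeric(values_nM))
  if (any(!is.finite(values_nM)) || any(values_nM <= 0)) {
    stop("aggregate_potency requires positive finite values; ",
         "non-positive values must be filtered upstream", call. = FALSE)
  }
  if (max(values_nM) / min(values_nM) > oom_window) {
    return(NA_real_)
  }
  9 - mean(log10(values_nM))
}

#' Build per-target, per-measurement-kind compound sets
#'
#' Joins filtered activity records to standardized structures, merges
#' structural duplicates (identical canonical SMILES under different
#' identifiers, same target and kind) before aggregation, aggregates
#' replicates by [aggregate_potency()], and drops compounds whose replicates
#' span more than one order of magnitude. Ki and IC50 records for the same
#' target always end up in distinct target sets.
#'
#' @param records filtered activity records (see [filter_activity_records()]).
#' @param molecules a `molecule_table` from [standardize_molecules()].
#' @param oom_window see [aggregate_potency()].
#' @return tibble of class `target_sets` with columns `target_id`,
#'   `measurement_kind`, `compound_id`, `canonical_smiles`, `pPotency`,
#'   sorted deterministically. When duplicates merge, the surviving
#'   `compound_id` is the smallest under C collation. Attributes:
#'   `n_no_structure` (records whose compound had no standardized structure),
#'   `n_oom_discarded` (compounds discarded by the replicate rule),
#'   `n_duplicates_merged` (identifier groups collapsed by structure).
#' @export
build_target_sets <- function(records, molecules, oom_window = 10) {
  mol <- valid_molecules(molecules)
  merged <- dplyr::inner_join(
    tibble::as_tibble(records),
    mol[, c("compound_id", "canonical_smiles")],
    by = "compound_id"
  )
  n_no_structure <- nrow(records) - nrow(merged)
  if (nrow(merged) == 0) {
    out <- tibble::tibble(target_id = character(),
                          measurement_kind = character(),
                          compound_id = character(),
                          canonical_smiles = character(),
                          pPotency = numeric())
    attr(out, "n_no_structure") <- n_no_structure
    attr(out, "n_oom_discarded") <- 0L
    attr(out, "n_duplicates_merged") <- 0L
    class(out) <- c("target_sets", class(out))
    return(out)
  }

  # structural duplicate merge: one member per (target, kind, structure)
  grp <- dplyr::group_by(merged, .data$target_id, .data$measurement_kind,
                         .data$canonical_smiles)
  agg <- dplyr::summarise(
    grp,
    n_ids = length(unique(.data$compound_id)),
    compound_id = sort(unique(.data$compound_id), method = "radix")[1],
    pPotency = aggregate_potency(.data$value_nM, oom_window = oom_window),
    .groups = "drop"
  )
  n_dup <- sum(agg$n_ids > 1)
  n_oom <- sum(is.na(agg$pPotency))
  out <- agg[!is.na(agg$pPotency),
             c("target_id", "measurement_kind", "compound_id",
               "canonical_smiles", "pPotency")]
  out <- out[radix_order(out$target_id, out$measurement_kind,
                         out$compound_id), , drop = FALSE]
  attr(out, "n_no_structure") <- n_no_structure
  attr(out, "n_oom_discarded") <- n_oom
  attr(out, "n_duplicates_merged") <- n_dup
  class(out) <- c("target_sets", class(out))
  out
}

#' Split a `target_sets` table into a list of single target sets
#'
#' @param target_sets result of [build_target_sets()].
#' @return named list of tibbles, one per (target_id, measurement_kind),
#'   names formatted `"<target_id>|<measurement_kind>"`, in C-collation order.
#' @export
split_target_sets <- function(target_sets) {
  key <- paste(target_sets$target_id, target_sets$measurement_kind, sep = "|")
  out <- split(tibble::as_tibble(target_sets), key)
  out[sort(names(out), method = "radix")]
}
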