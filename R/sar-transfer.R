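# Target-based SAR transfer series: pairs of analog series with distinct
# cores and corresponding substituents whose potencies progress in (at least
# approximately) the same rank order.

#' Extract analog series from a target set
#'
#' One series per canonical core occurring in at least one member; a
#' compound contributes to every core it exhibits. Each retained
#' (core, substituent) decomposition satisfies the per-cut size rules
#' (core at least `core_multiple` times the substituent, substituent at most
#' `max_frag` heavy atoms), mirroring the size-restricted MMP basis of the
#' series analysis.
#'
#' @param target_set single target set tibble (`compound_id`,
#'   `canonical_smiles`, `pPotency`, plus `target_id`, `measurement_kind`).
#' @param cuts cut table for the member molecules (standard fragmentation,
#'   hydrogen expansion included); computed on demand when `NULL`.
#' @param core_multiple,max_frag per-cut size parameters.
#' @return tibble of class `series_table`: `core`, `core_heavy`, `fragment`,
#'   `frag_heavy`, `compound_id`, `pPotency`, one row per series member,
#'   sorted by (core, fragment) under C collation.
#' @export
extract_series <- function(target_set, cuts = NULL, core_multiple = 2,
                           max_frag = 13) {
  if (is.null(cuts)) {
    mol <- tibble::tibble(compound_id = target_set$compound_id,
                          canonical_smiles = target_set$canonical_smiles)
    cuts <- enumerate_cuts(mol, hydrogen = TRUE)
  }
  cuts <- tibble::as_tibble(cuts)
  cuts <- cuts[cuts$core_heavy >= core_multiple * cuts$frag_heavy &
                 cuts$frag_heavy <= max_frag, , drop = FALSE]
  out <- dplyr::inner_join(
    cuts[, c("compound_id", "core", "core_heavy", "fragment", "frag_heavy")],
    tibble::as_tibble(target_set)[, c("compound_id", "pPotency")],
    by = "compound_id"
  )
  # one member per substituent per series; symmetric cut sites collapse,
  # and identifier order breaks the (structurally impossible) tie
  out <- out[radix_order(out$core, out$fragment, out$compound_id), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("core", "fragment")]), , drop = FALSE]
  out <- out[, c("core", "core_heavy", "fragment", "frag_heavy",
                 "compound_id", "pPotency")]
  class(out) <- c("series_table", class(out))
  out
}

#' Find matching series
#'
#' Every unordered pair of series with distinct cores whose substituent-key
#' intersection holds at least `min_pairs` corresponding analogs, and whose
#' matched-pair potencies span at least `min_span` orders of magnitude in
#' both series, is a matching series. The span is computed over the matched
#' pairs only, since the matched sub-series is the reported object.
#'
#' @param series `series_table` from [extract_series()].
#' @param min_pairs minimum number of corresponding analog pairs (default 3).
#' @param min_span minimum potency span per series, in orders of magnitude
#'   (default 2).
#' @return tibble of class `matching_series`: `core_a`, `core_b`
#'   (`core_a < core_b`, C collation), `n_pairs`, `span_a`, `span_b`, and a
#'   `pairs` list-column of tibbles (`fragment`, `cpd_a`, `cpd_b`, `pPot_a`,
#'   `pPot_b`, sorted by fragment).
#' @export
find_matching_series <- function(series, min_pairs = 3, min_span = 2) {
  ser <- tibble::as_tibble(series)
  empty <- tibble::tibble(core_a = character(), core_b = character(),
                          n_pairs = integer(), span_a = numeric(),
                          span_b = numeric(), pairs = list())
  class(empty) <- c("matching_series", class(empty))
  if (nrow(ser) == 0) return(empty)
  sizes <- table(ser$core)
  big <- names(sizes)[sizes >= min_pairs]
  ser <- ser[ser$core %in% big, , drop = FALSE]
  if (nrow(ser) == 0) return(empty)

  lhs <- ser
  names(lhs) <- paste0(names(lhs), "_a")
  rhs <- ser
  names(rhs) <- paste0(names(rhs), "_b")
  joined <- dplyr::inner_join(lhs, rhs, by = c(fragment_a = "fragment_b"),
                              relationship = "many-to-many")
  core_pool <- sort(unique(ser$core), method = "radix")
  joined <- joined[match(joined$core_a, core_pool) <
                     match(joined$core_b, core_pool), , drop = FALSE]
  if (nrow(joined) == 0) return(empty)

  key <- paste(joined$core_a, joined$core_b, sep = "\r")
  rows <- lapply(split(joined, key), function(d) {
    if (nrow(d) < min_pairs) return(NULL)
    span_a <- max(d$pPotency_a) - min(d$pPotency_a)
    span_b <- max(d$pPotency_b) - min(d$pPotency_b)
    if (span_a < min_span || span_b < min_span) return(NULL)
    d <- d[radix_order(d$fragment_a), , drop = FALSE]
    tibble::tibble(
      core_a = d$core_a[1], core_b = d$core_b[1],
      n_pairs = nrow(d), span_a = span_a, span_b = span_b,
      pairs = list(tibble::tibble(
        fragment = d$fragment_a,
        cpd_a = d$compound_id_a, cpd_b = d$compound_id_b,
        pPot_a = d$pPotency_a, pPot_b = d$pPotency_b
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- out[radix_order(out$core_a, out$core_b), , drop = FALSE]
  class(out) <- c("matching_series", class(out))
  out
}

#' Classify the potency progression of a matching series
#'
#' Pairs are ordered by the first series' potency (ties broken by substituent
#' SMILES under C collation) and the Spearman rank correlation between the
#' two series' potencies is computed. The progression is `"regular"` when the
#' rank orders correspond strictly — correlation exactly 1 with no ties
#' (within `tie_eps`) in either series — and `"approximate"` when the
#' correlation reaches `approx_threshold` without being regular; otherwise
#' `"none"`. A tie disqualifies the regular class.
#'
#' @param pairs tibble with columns `pPot_a`, `pPot_b` (and optionally
#'   `fragment`), or one row of a `matching_series` table.
#' @param approx_threshold Spearman correlation threshold for the
#'   approximate class (default 0.7).
#' @param tie_eps potencies closer than this count as tied (default 1e-9).
#' @return list with elements `progression` ("regular", "approximate" or
#'   "none") and `rank_correlation`.
#' @export
#' @examples
#' classify_progression(data.frame(pPot_a = c(5, 6, 7),
#'                                 pPot_b = c(6, 7, 8)))  # regular
classify_progression <- function(pairs, approx_threshold = 0.7,
                                 tie_eps = 1e-9) {
  if (is.data.frame(pairs) && "pairs" %in% names(pairs) && nrow(pairs) == 1) {
    pairs <- pairs$pairs[[1]]
  }
  stopifnot(all(c("pPot_a", "pPot_b") %in% names(pairs)))
  if (nrow(pairs) < 3) {
    stop("progression classification needs at least 3 pairs", call. = FALSE)
  }
  frag <- if ("fragment" %in% names(pairs)) pairs$fragment else
    as.character(seq_len(nrow(pairs)))
  o <- radix_order(pairs$pPot_a, frag)
  a <- pairs$pPot_a[o]
  b <- pairs$pPot_b[o]
  rho <- stats::cor(a, b, method = "spearman")
  tied <- function(x) any(abs(diff(sort(x))) < tie_eps)
  has_ties <- tied(a) || tied(b)
  regular <- !has_ties && isTRUE(all.equal(rho, 1, tolerance = 1e-12)) &&
    !is.unsorted(b)
  progression <- if (regular) {
    "regular"
  } else if (!is.na(rho) && rho >= approx_threshold) {
    "approximate"
  } else {
    "none"
  }
  list(progression = progression, rank_correlation = rho)
}

#' Classify all matching series of a target set
#'
#' @param matching `matching_series` table from [find_matching_series()].
#' @inheritParams classify_progression
#' @return `matching` with columns `progression` and `rank_correlation`
#'   appended; rows classified `"none"` are retained so that the nesting
#'   regular subset of transfer subset of matching is visible in one table.
#' @export
classify_matching_series <- function(matching, approx_threshold = 0.7,
                                     tie_eps = 1e-9) {
  out <- tibble::as_tibble(matching)
  if (nrow(out) == 0) {
    out$progression <- character(0)
    out$rank_correlation <- numeric(0)
    return(out)
  }
  cls <- lapply(out$pairs, classify_progression,
                approx_threshold = approx_threshold, tie_eps = tie_eps)
  out$progression <- vapply(cls, `[[`, "", "progression")
  out$rank_correlation <- vapply(cls, `[[`, 1.0, "rank_correlation")
  out
}
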