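# MMP assembly from a fragment index, transformation size restrictions,
# canonical pair selection, and activity-cliff detection.

#' Transformation size restrictions
#'
#' A candidate transformation is admitted when the shared core is at least
#' `core_multiple` (default 2) times the size of each exchanged fragment,
#' the two fragments differ by at most `max_diff` (default 8) heavy atoms,
#' and neither fragment exceeds `max_frag` (default 13) heavy atoms. All
#' sizes are counted in non-hydrogen atoms; the attachment point is never
#' counted. Vectorized.
#'
#' @param core_heavy,frag_a_heavy,frag_b_heavy integer vectors.
#' @param core_multiple,max_diff,max_frag rule parameters.
#' @return logical vector.
#' @export
#' @examples
#' apply_size_rules(26, 13, 5)  # TRUE (boundary)
#' apply_size_rules(20, 13, 4)  # FALSE (difference 9 > 8)
#' apply_size_rules(10, 6, 5)   # FALSE (10 < 2 * 6)
apply_size_rules <- function(core_heavy, frag_a_heavy, frag_b_heavy,
                             core_multiple = 2, max_diff = 8, max_frag = 13) {
  stopifnot(all(core_heavy >= 0), all(frag_a_heavy >= 0),
            all(frag_b_heavy >= 0))
  core_heavy >= core_multiple * frag_a_heavy &
    core_heavy >= core_multiple * frag_b_heavy &
    abs(frag_a_heavy - frag_b_heavy) <= max_diff &
    pmax(frag_a_heavy, frag_b_heavy) <= max_frag
}

empty_mmps <- function() {
  tibble::tibble(cpd_a = character(), cpd_b = character(),
                 core = character(), core_heavy = integer(),
                 frag_a = character(), frag_b = character(),
                 frag_a_heavy = integer(), frag_b_heavy = integer(),
                 transformation = character())
}

#' Assemble matched molecular pairs from a fragment index
#'
#' For every core key, every unordered pair of index entries with distinct
#' compounds and distinct fragments that passes [apply_size_rules()] yields a
#' candidate MMP. By default one canonical MMP is kept per compound pair
#' (see [select_canonical()]); with `exhaustive = TRUE` every admissible
#' (pair, transformation) record is returned.
#'
#' Pair orientation is normalized (`cpd_a < cpd_b` under C collation) and the
#' stored transformation is direction-normalized
#' (`frag_left >> frag_right` with `frag_left <= frag_right` under C
#' collation), so the output is invariant under permuting the input.
#'
#' @param index `fragment_index` from [build_fragment_index()].
#' @param core_multiple,max_diff,max_frag see [apply_size_rules()].
#' @param exhaustive keep all admissible transformations per pair.
#' @return tibble of class `mmp_table`: `cpd_a`, `cpd_b`, `core`,
#'   `core_heavy`, `frag_a`, `frag_b` (fragment observed in `cpd_a`,
#'   `cpd_b`), `frag_a_heavy`, `frag_b_heavy`, `transformation` (plus
#'   `rule_ids` for retrosynthetic indexes).
#' @export
assemble_mmps <- function(index, core_multiple = 2, max_diff = 8,
                          max_frag = 13, exhaustive = FALSE) {
  idx <- tibble::as_tibble(index)
  if (nrow(idx) == 0) return(empty_mmps())
  has_rules <- "rule_ids" %in% names(idx)
  lhs <- idx
  names(lhs) <- paste0(names(lhs), "_x")
  rhs <- idx
  names(rhs) <- paste0(names(rhs), "_y")
  pairs <- dplyr::inner_join(lhs, rhs, by = c(core_x = "core_y"),
                             relationship = "many-to-many")
  pairs <- pairs[pairs$compound_id_x != pairs$compound_id_y &
                   pairs$fragment_x != pairs$fragment_y, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty_mmps())
  # orient each pair once: cpd_a < cpd_b in C collation
  ids <- sort(unique(c(pairs$compound_id_x, pairs$compound_id_y)),
              method = "radix")
  keep <- match(pairs$compound_id_x, ids) < match(pairs$compound_id_y, ids)
  pairs <- pairs[keep, , drop = FALSE]
  ok <- apply_size_rules(pairs$core_heavy_x, pairs$frag_heavy_x,
                         pairs$frag_heavy_y, core_multiple = core_multiple,
                         max_diff = max_diff, max_frag = max_frag)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty_mmps())

  frag_pool <- sort(unique(c(pairs$fragment_x, pairs$fragment_y)),
                    method = "radix")
  left_first <- match(pairs$fragment_x, frag_pool) <=
    match(pairs$fragment_y, frag_pool)
  out <- tibble::tibble(
    cpd_a = pairs$compound_id_x,
    cpd_b = pairs$compound_id_y,
    core = pairs$core_x,
    core_heavy = pairs$core_heavy_x,
    frag_a = pairs$fragment_x,
    frag_b = pairs$fragment_y,
    frag_a_heavy = pairs$frag_heavy_x,
    frag_b_heavy = pairs$frag_heavy_y,
    transformation = paste0(
      ifelse(left_first, pairs$fragment_x, pairs$fragment_y), ">>",
      ifelse(left_first, pairs$fragment_y, pairs$fragment_x)
    )
  )
  if (has_rules) {
    ra <- strsplit(pairs$rule_ids_x, ",")
    rb <- strsplit(pairs$rule_ids_y, ",")
    # each side's cut is reaction-derived on its own; the pair-level record
    # carries the union of the rules that justified the two cuts
    out$rule_ids <- mapply(function(a, b) {
      paste(sort(unique(c(a, b)), method = "radix"), collapse = ",")
    }, ra, rb)
  }
  out <- out[!duplicated(out[, c("cpd_a", "cpd_b", "core",
                                 "transformation")]), , drop = FALSE]
  if (!exhaustive) out <- select_canonical(out)
  out <- out[radix_order(out$cpd_a, out$cpd_b, out$core,
                         out$transformation), , drop = FALSE]
  class(out) <- c("mmp_table", class(out))
  out
}

#' Select the canonical MMP per compound pair
#'
#' Among all admissible transformations relating the same unordered compound
#' pair, the canonical representative minimizes, in order: the larger
#' fragment's heavy-atom count, the total fragment heavy-atom count, and the
#' core SMILES under C collation. The winner is the transformation with the
#' largest shared context — the minimal single-site change.
#'
#' @param candidates `mmp_table` rows (possibly several compound pairs).
#' @return one row per unordered compound pair.
#' @export
select_canonical <- function(candidates) {
  cand <- tibble::as_tibble(candidates)
  if (nrow(cand) == 0) return(cand)
  o <- radix_order(cand$cpd_a, cand$cpd_b,
                   pmax(cand$frag_a_heavy, cand$frag_b_heavy),
                   cand$frag_a_heavy + cand$frag_b_heavy,
                   cand$core)
  cand <- cand[o, , drop = FALSE]
  cand[!duplicated(cand[, c("cpd_a", "cpd_b")]), , drop = FALSE]
}

#' Detect MMP-cliffs
#'
#' An MMP-cliff is an MMP whose partners' potencies differ by at least
#' `threshold_oom` orders of magnitude (default 2; the relaxed criterion
#' uses 1). Orientation is recorded from the less to the more potent
#' compound.
#'
#' @param mmps `mmp_table` from [assemble_mmps()].
#' @param target_set a single target set (tibble with `compound_id`,
#'   `pPotency`); every MMP compound must be present.
#' @param threshold_oom potency-difference threshold in orders of magnitude.
#' @return tibble of class `cliff_table`: MMP columns plus `cpd_low`,
#'   `cpd_high`, `pPot_low`, `pPot_high`, `delta`.
#' @export
detect_cliffs <- function(mmps, target_set, threshold_oom = 2) {
  stopifnot(is.numeric(threshold_oom), threshold_oom > 0)
  mmps <- tibble::as_tibble(mmps)
  pot <- stats::setNames(target_set$pPotency, target_set$compound_id)
  missing <- setdiff(unique(c(mmps$cpd_a, mmps$cpd_b)), names(pot))
  if (length(missing) > 0) {
    stop("compounds without potency in target set: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pa <- unname(pot[mmps$cpd_a])
  pb <- unname(pot[mmps$cpd_b])
  delta <- abs(pa - pb)
  out <- mmps[which(delta >= threshold_oom), , drop = FALSE]
  if (nrow(out) == 0) {
    out$cpd_low <- character(0)
    out$cpd_high <- character(0)
    out$pPot_low <- numeric(0)
    out$pPot_high <- numeric(0)
    out$delta <- numeric(0)
    class(out) <- c("cliff_table", class(out))
    return(out)
  }
  pa <- pa[delta >= threshold_oom]
  pb <- pb[delta >= threshold_oom]
  a_low <- pa <= pb
  out$cpd_low <- ifelse(a_low, out$cpd_a, out$cpd_b)
  out$cpd_high <- ifelse(a_low, out$cpd_b, out$cpd_a)
  out$pPot_low <- pmin(pa, pb)
  out$pPot_high <- pmax(pa, pb)
  out$delta <- abs(pa - pb)
  class(out) <- c("cliff_table", class(out))
  out
}

#' Independent size-rule audit over emitted MMPs
#'
#' Re-checks every emitted MMP against the size restrictions with inline
#' arithmetic (deliberately not routed through [apply_size_rules()]).
#'
#' @param mmps `mmp_table`.
#' @inheritParams apply_size_rules
#' @return logical vector, one entry per MMP.
#' @export
audit_size_rules <- function(mmps, core_multiple = 2, max_diff = 8,
                             max_frag = 13) {
  with(mmps, {
    big <- ifelse(frag_a_heavy > frag_b_heavy, frag_a_heavy, frag_b_heavy)
    small <- ifelse(frag_a_heavy > frag_b_heavy, frag_b_heavy, frag_a_heavy)
    (core_heavy >= core_multiple * big) &
      ((big - small) <= max_diff) &
      (big <= max_frag)
  })
}
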