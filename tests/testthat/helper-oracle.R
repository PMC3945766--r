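# Brute-force all-pairs MMP oracle: for every unordered compound pair,
# intersect the two cut lists on the core string, apply the size rules with
# inline arithmetic, and pick the canonical transformation by the
# largest-shared-context ordering. Deliberately written as plain nested
# loops, independent of the fragment-index implementation it checks.

brute_force_mmps <- function(cuts) {
  ids <- sort(unique(cuts$compound_id), method = "radix")
  by_id <- split(as.data.frame(cuts), cuts$compound_id)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(max(0L, i - 1L))) {
      A <- by_id[[ids[[j]]]]
      B <- by_id[[ids[[i]]]]
      best <- NULL
      for (x in seq_len(nrow(A))) {
        for (y in seq_len(nrow(B))) {
          if (A$core[x] != B$core[y]) next
          if (A$fragment[x] == B$fragment[y]) next
          ch <- A$core_heavy[x]
          fx <- A$frag_heavy[x]
          fy <- B$frag_heavy[y]
          if (ch < 2 * fx || ch < 2 * fy) next
          if (abs(fx - fy) > 8) next
          if (max(fx, fy) > 13) next
          fr <- sort(c(A$fragment[x], B$fragment[y]), method = "radix")
          cand <- list(core = A$core[x],
                       k1 = max(fx, fy), k2 = fx + fy,
                       trans = paste0(fr[1], ">>", fr[2]))
          if (is.null(best) || oracle_better(cand, best)) best <- cand
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1]] <- data.frame(
          cpd_a = ids[[j]], cpd_b = ids[[i]], core = best$core,
          transformation = best$trans, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cpd_a = character(0), cpd_b = character(0),
                      core = character(0), transformation = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$cpd_a, out$cpd_b, method = "radix"), , drop = FALSE]
}

oracle_better <- function(a, b) {
  if (a$k1 != b$k1) return(a$k1 < b$k1)
  if (a$k2 != b$k2) return(a$k2 < b$k2)
  sort(c(a$core, b$core), method = "radix")[1] == a$core && a$core != b$core
}
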