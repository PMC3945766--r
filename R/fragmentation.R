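# Systematic single-cut fragmentation and the core-keyed fragment index.
#
# Following the key-value idea of Hussain and Rea, every molecule is cut at
# every exocyclic single bond between two heavy atoms (each side serving once
# as the exchanged fragment), optionally augmented with hydrogen-expansion
# cuts; indexing the resulting (core, fragment) records by canonical core
# makes MMP detection a per-key pairing problem instead of an all-pairs
# structure comparison.

empty_cuts <- function() {
  tibble::tibble(compound_id = character(), core = character(),
                 fragment = character(), core_heavy = integer(),
                 frag_heavy = integer(), a1 = integer(), a2 = integer(),
                 kind = character())
}

cuts_from_backend <- function(molecules, hydrogen) {
  mol <- valid_molecules(molecules)
  if (nrow(mol) == 0) return(empty_cuts())
  raw <- chem_cuts(mol$canonical_smiles, hydrogen = hydrogen)
  if (nrow(raw) == 0) return(empty_cuts())
  map <- mol[, c("compound_id", "canonical_smiles")]
  out <- dplyr::inner_join(map, raw,
                           by = c(canonical_smiles = "smiles"),
                           relationship = "many-to-many")
  out$canonical_smiles <- NULL
  tibble::as_tibble(out)
}

#' Enumerate all single cuts of a set of molecules
#'
#' One cut per acyclic single bond between two heavy atoms and per
#' orientation: each side of the bond serves once as the exchanged fragment.
#' Ring-internal bonds, bonds to hydrogen, and double/triple/aromatic bonds
#' are never cut. With `hydrogen = TRUE` (the default), hydrogen-expansion
#' cuts are appended: for each symmetry-distinct hydrogen-bearing heavy-atom
#' position, a cut whose core is the whole molecule with an attachment point
#' at that position and whose fragment is the hydrogen pseudo-fragment.
#'
#' Each cut satisfies atom conservation (`core_heavy + frag_heavy` equals the
#' parent's heavy-atom count) and reassembles to the parent canonical SMILES
#' (see [audit_cuts()]).
#'
#' @param molecules a `molecule_table`, or a character vector of standardized
#'   SMILES.
#' @param hydrogen include hydrogen-expansion cuts.
#' @return tibble with columns `compound_id`, `core`, `fragment`,
#'   `core_heavy`, `frag_heavy`, `a1`, `a2` (atom indices of the cut bond;
#'   `a2 = -1` for hydrogen expansion), `kind`.
#' @export
enumerate_cuts <- function(molecules, hydrogen = TRUE) {
  if (is.character(molecules)) {
    molecules <- tibble::tibble(compound_id = molecules,
                                canonical_smiles = molecules)
  }
  cuts_from_backend(molecules, hydrogen = hydrogen)
}

#' @rdname enumerate_cuts
#' @export
enumerate_single_cuts <- function(molecules) {
  enumerate_cuts(molecules, hydrogen = FALSE)
}

#' Hydrogen-expansion cuts only
#'
#' @inheritParams enumerate_cuts
#' @return as [enumerate_cuts()], restricted to `kind == "hydrogen"`.
#' @export
hydrogen_expansion <- function(molecules) {
  cuts <- enumerate_cuts(molecules, hydrogen = TRUE)
  cuts[cuts$kind == "hydrogen", , drop = FALSE]
}

#' Build the core-keyed fragment index
#'
#' Deduplicates (compound, core, fragment) triples and orders entries by
#' (core, compound_id, fragment) under C collation so the index — and
#' everything derived from it — is deterministic.
#'
#' @param cuts cut table from [enumerate_cuts()] or [enumerate_retro_cuts()].
#' @return tibble of class `fragment_index` with columns `core`,
#'   `core_heavy`, `compound_id`, `fragment`, `frag_heavy` (plus `rule_ids`
#'   when present in the input).
#' @export
build_fragment_index <- function(cuts) {
  keep <- c("core", "core_heavy", "compound_id", "fragment", "frag_heavy",
            intersect("rule_ids", names(cuts)))
  idx <- tibble::as_tibble(cuts)[, keep]
  idx <- idx[!duplicated(idx[, c("core", "compound_id", "fragment")]), ,
             drop = FALSE]
  idx <- idx[radix_order(idx$core, idx$compound_id, idx$fragment), ,
             drop = FALSE]
  class(idx) <- c("fragment_index", class(idx))
  idx
}

#' Write a per-compound cut table (debug output)
#'
#' @param cuts cut table.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_cut_table <- function(cuts, path) {
  cols <- c("compound_id", "core", "fragment", "core_heavy", "frag_heavy")
  write_tsv(tibble::as_tibble(cuts)[, cols], path)
}

#' Audit cuts for reassembly and atom conservation
#'
#' Independently re-checks the two cut invariants: reattaching fragment to
#' core reproduces the parent canonical SMILES, and core plus fragment heavy
#' atoms sum to the parent heavy-atom count.
#'
#' @param cuts cut table with `compound_id`, `core`, `fragment`,
#'   `core_heavy`, `frag_heavy`.
#' @param molecules `molecule_table` giving, per `compound_id`, the parent
#'   `canonical_smiles` and `heavy_atoms`.
#' @return the cut table with logical columns `reassembles` and `conserves`.
#' @export
audit_cuts <- function(cuts, molecules) {
  mol <- valid_molecules(molecules)
  out <- dplyr::inner_join(
    tibble::as_tibble(cuts),
    mol[, c("compound_id", "canonical_smiles", "heavy_atoms")],
    by = "compound_id"
  )
  rejoined <- chem_reassemble(out$core, out$fragment)
  out$reassembles <- !is.na(rejoined) & rejoined == out$canonical_smiles
  out$conserves <- (out$core_heavy + out$frag_heavy) == out$heavy_atoms
  out
}
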