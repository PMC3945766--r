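# Structure ingestion and standardization.

#' Standardize a table of compounds
#'
#' Parses each SMILES, keeps the largest organic covalent component (salt and
#' solvent stripping), neutralizes charges where a proton can be added or
#' removed without exceeding standard valence, and computes the canonical
#' SMILES and heavy-atom count. Stereochemistry is preserved as given.
#' Unparsable records are kept in the output with `canonical_smiles = NA`
#' and the failure reason in `error`; downstream stages skip them.
#'
#' @param compounds data frame with columns `compound_id` and `smiles`, or a
#'   character vector of SMILES (identifiers are then generated).
#' @return tibble of class `molecule_table` with columns `compound_id`,
#'   `input_smiles`, `canonical_smiles`, `heavy_atoms`, `error`. The
#'   canonical SMILES always encodes a single covalently connected component
#'   and re-canonicalizes to itself.
#' @export
#' @examples
#' \dontrun{
#' standardize_molecules(c("CCO", "CCO.[Na+].[Cl-]", "CC(=O)[O-]"))
#' }
standardize_molecules <- function(compounds) {
  if (is.character(compounds)) {
    compounds <- tibble::tibble(
      compound_id = sprintf("M%04d", seq_along(compounds)),
      smiles = compounds
    )
  }
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicate compound_id in compound table", call. = FALSE)
  }
  std <- chem_standardize(as.character(compounds$smiles))
  out <- tibble::tibble(
    compound_id = as.character(compounds$compound_id),
    input_smiles = std$input_smiles,
    canonical_smiles = std$canonical_smiles,
    heavy_atoms = std$heavy_atoms,
    error = std$error
  )
  n_failed <- sum(is.na(out$canonical_smiles))
  attr(out, "n_failed") <- n_failed
  class(out) <- c("molecule_table", class(out))
  out
}

#' Standardize a single SMILES string
#'
#' @param raw_smiles a single SMILES string.
#' @return one-row `molecule_table` (see [standardize_molecules()]).
#'   Unparsable input raises an error.
#' @export
standardize <- function(raw_smiles) {
  stopifnot(is.character(raw_smiles), length(raw_smiles) == 1)
  out <- standardize_molecules(raw_smiles)
  if (is.na(out$canonical_smiles)) {
    stop("cannot standardize '", raw_smiles, "': ", out$error, call. = FALSE)
  }
  out
}

#' Read a SMILES file
#'
#' One record per line: SMILES, whitespace, identifier. Lines without an
#' identifier get a generated one.
#'
#' @param path file path.
#' @return tibble with columns `compound_id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  tibble::tibble(
    compound_id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][[2]] else sprintf("M%04d", i)
    }, ""),
    smiles = vapply(parts, `[[`, "", 1)
  )
}

#' Drop molecules that failed standardization
#' @param molecules a `molecule_table`.
#' @return the table restricted to successfully standardized records.
#' @export
valid_molecules <- function(molecules) {
  molecules[!is.na(molecules$canonical_smiles), , drop = FALSE]
}
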