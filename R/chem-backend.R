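# Bridge to the bundled RDKit helper (inst/python/chem_backend.py).
#
# Every wrapper is batched: one subprocess invocation per *vector* of
# molecules, never per molecule, and results are memoised per input string in
# a package-local cache so repeated pipeline runs in one session do not pay
# the interpreter start-up cost again.

.mmpairs_cache <- new.env(parent = emptyenv())

#' Hydrogen pseudo-fragment token
#'
#' The substituent string used to represent a hydrogen atom in cut and
#' transformation records. It counts as 0 heavy atoms and trivially satisfies
#' the core-size rule, which is what permits transformations such as the
#' addition of a substituted ring to an unsubstituted position.
#' @export
H_FRAGMENT <- "[*][H]"

chem_python <- function() {
  opt <- getOption("mmpairs.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("MMPAIRS_PYTHON", "")
  if (nzchar(env)) return(env)
  "python"
}

backend_script <- function() {
  system.file("python", "chem_backend.py", package = "mmpairs",
              mustWork = TRUE)
}

cache_env <- function(name) {
  if (is.null(.mmpairs_cache[[name]])) {
    .mmpairs_cache[[name]] <- new.env(parent = emptyenv())
  }
  .mmpairs_cache[[name]]
}

#' @noRd
chem_call <- function(op, payload) {
  req <- jsonlite::toJSON(list(op = op, payload = payload),
                          auto_unbox = TRUE, digits = NA, null = "null")
  err_file <- tempfile("mmpairs-backend-err-")
  on.exit(unlink(err_file), add = TRUE)
  out <- suppressWarnings(
    system2(chem_python(), shQuote(backend_script()), input = req,
            stdout = TRUE, stderr = err_file)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    msg <- tryCatch(paste(readLines(err_file), collapse = "\n"),
                    error = function(e) "")
    stop("chemistry backend failed (exit ", status, "): ", msg, call. = FALSE)
  }
  resp <- jsonlite::fromJSON(paste(out, collapse = ""),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!isTRUE(resp$ok)) {
    stop("chemistry backend error: ", resp$error, call. = FALSE)
  }
  resp$result
}

# turn the backend's parallel-array result into a tibble, tolerating empties
result_tibble <- function(result, cols) {
  vals <- lapply(cols, function(cn) {
    v <- result[[cn]]
    if (is.null(v) || length(v) == 0) return(vector("character", 0))
    if (is.list(v)) v <- unlist(lapply(v, function(x) if (is.null(x)) NA else x))
    v
  })
  names(vals) <- cols
  n <- max(vapply(vals, length, 1L), 0L)
  vals <- lapply(vals, function(v) if (length(v) < n) rep(v, length.out = n) else v)
  tibble::as_tibble(vals)
}

#' Standardize SMILES strings through the chemistry backend
#'
#' Applies largest-organic-component selection (salt/solvent stripping),
#' charge neutralization where a proton can be added or removed without
#' exceeding standard valence, and canonical SMILES generation.
#' Unparsable records are returned with `canonical_smiles = NA` and a
#' per-record error message rather than aborting the batch.
#'
#' @param smiles character vector of raw SMILES.
#' @return tibble with columns `input_smiles`, `canonical_smiles`
#'   (NA on failure), `heavy_atoms`, `error`.
#' @keywords internal
chem_standardize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(tibble::tibble(input_smiles = character(),
                          canonical_smiles = character(),
                          heavy_atoms = integer(), error = character()))
  }
  env <- cache_env("standardize")
  missing <- unique(smiles[!vapply(smiles, exists, TRUE, envir = env)])
  if (length(missing) > 0) {
    res <- chem_call("standardize", list(
      records = lapply(seq_along(missing), function(i) {
        list(id = i, smiles = missing[[i]])
      })
    ))
    tab <- result_tibble(res, c("input_smiles", "canonical_smiles",
                                "heavy_atoms", "error"))
    for (i in seq_len(nrow(tab))) {
      assign(missing[[i]], as.list(tab[i, ]), envir = env)
    }
  }
  rows <- lapply(smiles, function(s) {
    r <- get(s, envir = env)
    tibble::tibble(input_smiles = s,
                   canonical_smiles = as.character(r$canonical_smiles),
                   heavy_atoms = as.integer(r$heavy_atoms),
                   error = as.character(r$error))
  })
  dplyr::bind_rows(rows)
}

#' Enumerate cuts for a batch of molecules
#'
#' @param smiles character vector of (standardized) SMILES; one entry per
#'   molecule, duplicates allowed.
#' @param hydrogen also emit hydrogen-expansion cuts.
#' @return tibble with columns `smiles`, `core`, `fragment`, `core_heavy`,
#'   `frag_heavy`, `a1`, `a2`, `kind` ("bond" or "hydrogen").
#' @keywords internal
chem_cuts <- function(smiles, hydrogen = TRUE) {
  stopifnot(is.character(smiles))
  env <- cache_env(if (hydrogen) "cuts_h" else "cuts")
  uniq <- unique(smiles)
  missing <- uniq[!vapply(uniq, exists, TRUE, envir = env)]
  if (length(missing) > 0) {
    res <- chem_call("cuts", list(
      records = lapply(missing, function(s) list(id = s, smiles = s)),
      hydrogen = hydrogen
    ))
    tab <- result_tibble(res, c("id", "core", "fragment", "core_heavy",
                                "frag_heavy", "a1", "a2", "kind"))
    tab$core_heavy <- as.integer(tab$core_heavy)
    tab$frag_heavy <- as.integer(tab$frag_heavy)
    tab$a1 <- as.integer(tab$a1)
    tab$a2 <- as.integer(tab$a2)
    for (s in missing) {
      assign(s, tab[tab$id == s, -1, drop = FALSE], envir = env)
    }
  }
  rows <- lapply(smiles, function(s) {
    cuts <- get(s, envir = env)
    if (nrow(cuts) == 0) return(cuts)
    tibble::as_tibble(cbind(smiles = s, cuts))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(smiles = character(), core = character(),
                          fragment = character(), core_heavy = integer(),
                          frag_heavy = integer(), a1 = integer(),
                          a2 = integer(), kind = character())
  }
  out
}

#' Reattach core and fragment at their attachment points
#'
#' @param core character vector of core SMILES, each with one attachment atom.
#' @param fragment character vector of fragment SMILES (or [H_FRAGMENT]).
#' @return character vector of canonical SMILES of the reassembled molecules
#'   (NA where reassembly failed).
#' @keywords internal
chem_reassemble <- function(core, fragment) {
  stopifnot(length(core) == length(fragment))
  if (length(core) == 0) return(character(0))
  env <- cache_env("reassemble")
  key <- paste(core, fragment, sep = " >> ")
  uniq <- !duplicated(key) & !vapply(key, exists, TRUE, envir = env)
  if (any(uniq)) {
    res <- chem_call("reassemble", list(
      records = mapply(function(cc, ff) list(core = cc, fragment = ff),
                       core[uniq], fragment[uniq],
                       SIMPLIFY = FALSE, USE.NAMES = FALSE)
    ))
    tab <- result_tibble(res, c("smiles", "error"))
    kk <- key[uniq]
    for (i in seq_along(kk)) {
      if (nzchar(tab$error[[i]])) {
        assign(kk[[i]], NA_character_, envir = env)
      } else {
        assign(kk[[i]], tab$smiles[[i]], envir = env)
      }
    }
  }
  vapply(key, get, "", envir = env, USE.NAMES = FALSE)
}

#' Match retrosynthetic rule SMARTS onto molecules
#'
#' @param smiles character vector of molecule SMILES.
#' @param rules tibble with columns `rule_id`, `smarts` (mapped atoms `:1`
#'   and `:2` define the cleavable bond).
#' @return tibble `smiles`, `rule_id`, `a1`, `a2`, `bond_order` with one row
#'   per matched acyclic bond per rule.
#' @keywords internal
chem_retro_bonds <- function(smiles, rules) {
  stopifnot(is.character(smiles), is.data.frame(rules))
  rules_key <- paste(rules$rule_id, rules$smarts, sep = "\r", collapse = "\n")
  env <- cache_env("retro")
  uniq <- unique(smiles)
  # note: paste() recycles a zero-length vector against the scalar key
  key <- if (length(uniq) == 0) character(0) else
    paste(uniq, rules_key, sep = "\f")
  missing <- uniq[!vapply(key, exists, TRUE, envir = env)]
  rule_recs <- mapply(function(id, sm) list(rule_id = id, smarts = sm),
                      rules$rule_id, rules$smarts,
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (length(missing) > 0 || length(uniq) == 0) {
    res <- chem_call("retro_bonds", list(
      records = lapply(missing, function(s) list(id = s, smiles = s)),
      rules = rule_recs
    ))
    tab <- result_tibble(res, c("id", "rule_id", "a1", "a2", "bond_order"))
    tab$a1 <- as.integer(tab$a1)
    tab$a2 <- as.integer(tab$a2)
    tab$bond_order <- as.integer(tab$bond_order)
    for (s in missing) {
      assign(paste(s, rules_key, sep = "\f"),
             tab[tab$id == s, -1, drop = FALSE], envir = env)
    }
  }
  rows <- lapply(smiles, function(s) {
    hits <- get(paste(s, rules_key, sep = "\f"), envir = env)
    if (nrow(hits) == 0) return(hits)
    tibble::as_tibble(cbind(smiles = s, hits))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(smiles = character(), rule_id = character(),
                          a1 = integer(), a2 = integer(),
                          bond_order = integer())
  }
  out
}

#' Cut one specific bond of a molecule (both orientations)
#' @keywords internal
chem_cut_bond <- function(smiles, a1, a2) {
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(), core = character(),
                          fragment = character(), core_heavy = integer(),
                          frag_heavy = integer(), a1 = integer(),
                          a2 = integer(), kind = character()))
  }
  res <- chem_call("cut_bond", list(
    records = mapply(function(s, i, j) list(id = s, smiles = s, a1 = i, a2 = j),
                     smiles, a1, a2, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  ))
  tab <- result_tibble(res, c("id", "core", "fragment", "core_heavy",
                              "frag_heavy", "a1", "a2", "kind"))
  names(tab)[1] <- "smiles"
  tab$core_heavy <- as.integer(tab$core_heavy)
  tab$frag_heavy <- as.integer(tab$frag_heavy)
  tab$a1 <- as.integer(tab$a1)
  tab$a2 <- as.integer(tab$a2)
  tab
}

#' Count heavy atoms of a fragment SMILES
#'
#' Counts non-hydrogen, non-attachment atoms of a fragment carrying at most
#' one attachment (wildcard) atom. The hydrogen pseudo-fragment counts 0.
#'
#' @param fragment_smiles character vector of fragment SMILES.
#' @return integer vector of heavy-atom counts.
#' @export
#' @examples
#' \dontrun{
#' heavy_atoms(c("[*]C", "[*]c1ccccc1", H_FRAGMENT))  # 1, 6, 0
#' }
heavy_atoms <- function(fragment_smiles) {
  stopifnot(is.character(fragment_smiles))
  if (length(fragment_smiles) == 0) return(integer(0))
  env <- cache_env("heavy")
  missing <- unique(fragment_smiles[!vapply(fragment_smiles, exists, TRUE,
                                            envir = env)])
  if (length(missing) > 0) {
    res <- chem_call("heavy_atoms", list(fragments = as.list(missing)))
    tab <- result_tibble(res, c("smiles", "heavy_atoms", "error"))
    for (i in seq_len(nrow(tab))) {
      if (nzchar(tab$error[[i]])) {
        assign(tab$smiles[[i]], tab$error[[i]], envir = env)
      } else {
        assign(tab$smiles[[i]], as.integer(tab$heavy_atoms[[i]]), envir = env)
      }
    }
  }
  out <- lapply(fragment_smiles, get, envir = env)
  bad <- vapply(out, is.character, TRUE)
  if (any(bad)) {
    stop("heavy_atoms: ", out[[which(bad)[1]]], " (",
         fragment_smiles[which(bad)[1]], ")", call. = FALSE)
  }
  vapply(out, identity, 1L)
}

# locale-independent (C-collation) ordering used everywhere determinism
# depends on string comparisons
radix_order <- function(...) order(..., method = "radix")

radix_rank <- function(x, table = x) {
  match(x, sort(unique(table), method = "radix"))
}
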