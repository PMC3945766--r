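# Pipeline orchestration, configuration, readers/writers, and the JSON run
# report whose counters mirror the published MMP / MMP-cliff / SAR-transfer /
# RECAP-MMP statistics tables.

#' Default activity-table column map
#'
#' Maps the pipeline's canonical field names to the column names of the
#' input activity table; override entries to adapt to other dialects.
#' @return named character vector.
#' @export
default_column_map <- function() {
  c(compound_id = "compound_id", target_id = "target_id",
    measurement_kind = "measurement_kind", relation = "relation",
    value_nM = "value_nM", confidence_score = "confidence_score",
    relationship_type = "relationship_type")
}

#' Pipeline configuration
#'
#' Defaults reproduce the reference parameterization: transformation size
#' rules core >= 2 x fragment, fragment size difference <= 8, fragment size
#' <= 13 heavy atoms; cliff thresholds 1 and 2 orders of magnitude;
#' SAR-transfer criteria of >= 3 corresponding analog pairs spanning >= 2
#' orders of magnitude, with approximate progression at Spearman rho >= 0.7;
#' replicate aggregation window of one order of magnitude (inclusive);
#' hydrogen expansion enabled for standard fragmentation.
#'
#' @param cliff_thresholds numeric vector of potency-difference thresholds
#'   (orders of magnitude).
#' @param core_multiple,max_diff,max_frag size-rule parameters
#'   (see [apply_size_rules()]).
#' @param scheme fragmentation scheme(s) to run: `"standard"`, `"recap"`, or
#'   `"both"`.
#' @param hydrogen_expansion include hydrogen-expansion cuts in standard
#'   fragmentation.
#' @param min_pairs,min_span,approx_threshold SAR-transfer parameters.
#' @param oom_window replicate window (nM ratio) for [aggregate_potency()].
#' @param rules_file retrosynthetic rule file (NULL = shipped default).
#' @param seed integer seed recorded in the report.
#' @param column_map see [default_column_map()].
#' @param exhaustive also emit the exhaustive per-(pair, transformation) MMP
#'   list next to the canonical pair-level list.
#' @return a `mmp_config` list.
#' @export
mmp_config <- function(cliff_thresholds = c(1, 2), core_multiple = 2,
                       max_diff = 8, max_frag = 13, scheme = "both",
                       hydrogen_expansion = TRUE, min_pairs = 3,
                       min_span = 2, approx_threshold = 0.7,
                       oom_window = 10, rules_file = NULL, seed = 1,
                       column_map = default_column_map(),
                       exhaustive = FALSE) {
  scheme <- match.arg(scheme, c("standard", "recap", "both"))
  stopifnot(all(cliff_thresholds > 0))
  structure(list(cliff_thresholds = sort(cliff_thresholds),
                 core_multiple = core_multiple, max_diff = max_diff,
                 max_frag = max_frag, scheme = scheme,
                 hydrogen_expansion = hydrogen_expansion,
                 min_pairs = min_pairs, min_span = min_span,
                 approx_threshold = approx_threshold,
                 oom_window = oom_window, rules_file = rules_file,
                 seed = seed, column_map = column_map,
                 exhaustive = exhaustive),
            class = "mmp_config")
}

#' Read an activity table
#'
#' @param path delimited text file (TSV by default).
#' @param column_map named character vector mapping canonical field names to
#'   file columns; see [default_column_map()].
#' @param sep field separator.
#' @return tibble with canonical column names.
#' @export
read_activity_table <- function(path, column_map = default_column_map(),
                                sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(unname(column_map), names(tab))
  if (length(miss) > 0) {
    stop("activity table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "),
         "; adjust the column map if the file uses other names",
         call. = FALSE)
  }
  out <- tab[, unname(column_map), drop = FALSE]
  names(out) <- names(column_map)
  tibble::as_tibble(out)
}

#' Read a compound table
#'
#' @param path delimited text file with an identifier and a SMILES column.
#' @param id_col,smiles_col column names.
#' @param sep field separator.
#' @return tibble with columns `compound_id`, `smiles`.
#' @export
read_compound_table <- function(path, id_col = "compound_id",
                                smiles_col = "smiles", sep = "\t") {
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c(id_col, smiles_col), names(tab))
  if (length(miss) > 0) {
    stop("compound table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(compound_id = as.character(tab[[id_col]]),
                 smiles = as.character(tab[[smiles_col]]))
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (cn in names(df)) {
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]])) {
      df[[cn]] <- formatC(df[[cn]], digits = 15, format = "g")
    }
  }
  con <- file(path, open = "wb")  # fixed \n line endings on every platform
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

slug <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Run the full MMP data-generation pipeline
#'
#' Standardizes structures, filters activity records, builds per-target /
#' per-measurement-kind target sets, and per target set: enumerates cuts,
#' builds the fragment index, assembles size-restricted MMPs, detects
#' cliffs at each configured threshold, optionally assembles retrosynthetic
#' MMPs, extracts analog series and identifies SAR transfer series. Ki and
#' IC50 subsets are processed independently throughout; cross-kind pairs are
#' never formed.
#'
#' @param compounds data frame `compound_id`, `smiles`.
#' @param activities activity records with canonical column names (use
#'   [read_activity_table()] for files).
#' @param config a [mmp_config()].
#' @param out_dir when non-NULL, per-target TSVs, a JSON run report and a
#'   filter log are written beneath it (one file per target, artifact kind
#'   and measurement kind); two runs with identical inputs, config and seed
#'   produce byte-identical trees.
#' @return list with elements `molecules`, `records`, `target_sets`,
#'   `mmps`, `cliffs`, `recap_mmps`, `series`, `matching`, `report`, and
#'   (when `exhaustive`) `mmps_exhaustive`.
#' @export
run_mmp_pipeline <- function(compounds, activities, config = mmp_config(),
                             out_dir = NULL) {
  stopifnot(inherits(config, "mmp_config"))
  molecules <- standardize_molecules(compounds)
  records <- filter_activity_records(activities)
  target_sets <- build_target_sets(records, molecules,
                                   oom_window = config$oom_window)
  sets <- split_target_sets(target_sets)
  rules <- if (config$scheme %in% c("recap", "both")) {
    read_retro_rules(config$rules_file)
  } else NULL

  mmps <- list()
  mmps_ex <- list()
  cliffs <- list()
  recap_mmps <- list()
  series_all <- list()
  matching_all <- list()

  for (nm in names(sets)) {
    ts <- sets[[nm]]
    mol <- tibble::tibble(compound_id = ts$compound_id,
                          canonical_smiles = ts$canonical_smiles)
    meta <- function(df) {
      if (nrow(df) > 0) {
        df$target_id <- ts$target_id[1]
        df$measurement_kind <- ts$measurement_kind[1]
      } else {
        df$target_id <- character(0)
        df$measurement_kind <- character(0)
      }
      df
    }
    if (config$scheme %in% c("standard", "both")) {
      cuts <- enumerate_cuts(mol, hydrogen = config$hydrogen_expansion)
      idx <- build_fragment_index(cuts)
      mm <- assemble_mmps(idx, core_multiple = config$core_multiple,
                          max_diff = config$max_diff,
                          max_frag = config$max_frag)
      mmps[[nm]] <- meta(mm)
      if (config$exhaustive) {
        mmps_ex[[nm]] <- meta(assemble_mmps(
          idx, core_multiple = config$core_multiple,
          max_diff = config$max_diff, max_frag = config$max_frag,
          exhaustive = TRUE))
      }
      for (t in config$cliff_thresholds) {
        cl <- detect_cliffs(mm, ts, threshold_oom = t)
        cliffs[[paste0(nm, "|", t)]] <- meta(cl)
      }
      ser <- extract_series(ts, cuts, core_multiple = config$core_multiple,
                            max_frag = config$max_frag)
      series_all[[nm]] <- meta(ser)
      mat <- find_matching_series(ser, min_pairs = config$min_pairs,
                                  min_span = config$min_span)
      mat <- classify_matching_series(
        mat, approx_threshold = config$approx_threshold)
      matching_all[[nm]] <- meta(mat)
    }
    if (config$scheme %in% c("recap", "both")) {
      rcuts <- enumerate_retro_cuts(mol, rules)
      ridx <- build_fragment_index(rcuts)
      rmm <- assemble_mmps(ridx, core_multiple = config$core_multiple,
                           max_diff = config$max_diff,
                           max_frag = config$max_frag)
      recap_mmps[[nm]] <- meta(rmm)
    }
  }

  empty_meta_mmps <- function() {
    out <- empty_mmps()
    out$target_id <- character(0)
    out$measurement_kind <- character(0)
    out
  }
  bind_named <- function(lst, fallback_cols) {
    if (length(lst) == 0) return(fallback_cols)
    dplyr::bind_rows(lst)
  }
  mmps_tab <- bind_named(mmps, empty_meta_mmps())
  recap_tab <- bind_named(recap_mmps, empty_meta_mmps())
  cliffs_tab <- lapply(
    stats::setNames(config$cliff_thresholds, config$cliff_thresholds),
    function(t) {
      keep <- grepl(paste0("\\|", t, "$"), names(cliffs))
      if (!any(keep)) return(empty_meta_mmps())
      dplyr::bind_rows(cliffs[keep])
    })
  series_tab <- bind_named(series_all, tibble::tibble(
    core = character(), core_heavy = integer(), fragment = character(),
    frag_heavy = integer(), compound_id = character(),
    pPotency = numeric(), target_id = character(),
    measurement_kind = character()))
  matching_tab <- bind_named(matching_all, tibble::tibble(
    core_a = character(), core_b = character(), n_pairs = integer(),
    span_a = numeric(), span_b = numeric(), pairs = list(),
    target_id = character(), measurement_kind = character(),
    progression = character(), rank_correlation = numeric()))

  report <- pipeline_report(molecules, records, target_sets, mmps_tab,
                            cliffs_tab, recap_tab, matching_tab, config)
  result <- list(molecules = molecules, records = records,
                 target_sets = target_sets, mmps = mmps_tab,
                 cliffs = cliffs_tab, recap_mmps = recap_tab,
                 series = series_tab, matching = matching_tab,
                 report = report, config = config)
  if (config$exhaustive) {
    result$mmps_exhaustive <- bind_named(mmps_ex, empty_mmps())
  }
  if (!is.null(out_dir)) {
    write_run_outputs(result, target_sets, out_dir)
  }
  result
}

pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else 0

#' Build the JSON-ready run report
#'
#' Counters per measurement kind: target sets, compounds, measurements;
#' pair-level MMP counts with targets and compound coverage; cliff counts,
#' proportions and coverage at each threshold; matching / SAR transfer /
#' regular series counts and target coverage; retrosynthetic MMP counts and
#' coverage; curation drop counters.
#' @keywords internal
pipeline_report <- function(molecules, records, target_sets, mmps, cliffs,
                            recap_mmps, matching, config) {
  kinds <- MEASUREMENT_KINDS
  per_kind <- lapply(stats::setNames(kinds, kinds), function(k) {
    ts <- target_sets[target_sets$measurement_kind == k, , drop = FALSE]
    mm <- mmps[mmps$measurement_kind == k, , drop = FALSE]
    rc <- recap_mmps[recap_mmps$measurement_kind == k, , drop = FALSE]
    n_cpd <- nrow(ts)
    cliff_part <- lapply(
      stats::setNames(names(cliffs), paste0("oom_", names(cliffs))),
      function(t) {
        cl <- cliffs[[t]]
        cl <- cl[cl$measurement_kind == k, , drop = FALSE]
        list(
          mmp_cliffs = nrow(cl),
          pct_of_mmps = pct(nrow(cl), nrow(mm)),
          targets_with_cliffs = length(unique(cl$target_id)),
          cliff_compounds = length(unique(c(cl$cpd_a, cl$cpd_b)))
        )
      })
    n_match <- if (nrow(matching) > 0) {
      sum(matching$measurement_kind == k)
    } else 0L
    mk <- if (nrow(matching) > 0) {
      matching[matching$measurement_kind == k, , drop = FALSE]
    } else matching
    n_transfer <- if (nrow(mk) > 0) {
      sum(mk$progression %in% c("regular", "approximate"))
    } else 0L
    n_regular <- if (nrow(mk) > 0) sum(mk$progression == "regular") else 0L
    transfer_targets <- if (nrow(mk) > 0) {
      length(unique(mk$target_id[mk$progression %in%
                                   c("regular", "approximate")]))
    } else 0L
    regular_targets <- if (nrow(mk) > 0) {
      length(unique(mk$target_id[mk$progression == "regular"]))
    } else 0L
    list(
      targets = length(unique(ts$target_id)),
      compounds = n_cpd,
      measurements = sum(records$measurement_kind == k),
      mmps = nrow(mm),
      targets_with_mmps = length(unique(mm$target_id)),
      mmp_compounds = length(unique(c(mm$cpd_a, mm$cpd_b))),
      pct_mmp_compounds = pct(length(unique(c(mm$cpd_a, mm$cpd_b))), n_cpd),
      cliffs = cliff_part,
      matching_series = n_match,
      sar_transfer_series = n_transfer,
      targets_with_sar_transfer = transfer_targets,
      sar_transfer_series_regular = n_regular,
      targets_with_sar_transfer_regular = regular_targets,
      recap_mmps = nrow(rc),
      targets_with_recap_mmps = length(unique(rc$target_id)),
      recap_mmp_compounds = length(unique(c(rc$cpd_a, rc$cpd_b)))
    )
  })
  list(
    config = list(
      cliff_thresholds = config$cliff_thresholds,
      core_multiple = config$core_multiple, max_diff = config$max_diff,
      max_frag = config$max_frag, scheme = config$scheme,
      hydrogen_expansion = config$hydrogen_expansion,
      min_pairs = config$min_pairs, min_span = config$min_span,
      approx_threshold = config$approx_threshold,
      oom_window = config$oom_window, seed = config$seed
    ),
    curation = list(
      structures_failed = attr(molecules, "n_failed"),
      filter_drops = as.list(attr(records, "drop_counts")),
      records_retained = nrow(records),
      no_structure = attr(target_sets, "n_no_structure"),
      oom_discarded = attr(target_sets, "n_oom_discarded"),
      duplicates_merged = attr(target_sets, "n_duplicates_merged")
    ),
    by_kind = per_kind
  )
}

write_run_outputs <- function(result, target_sets, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(out_dir, "targets")
  dir.create(tdir, showWarnings = FALSE)
  smiles_of <- stats::setNames(target_sets$canonical_smiles,
                               target_sets$compound_id)
  pot_of <- stats::setNames(target_sets$pPotency, target_sets$compound_id)

  write_pairs <- function(df, artifact, scheme) {
    if (nrow(df) == 0) return(invisible(NULL))
    key <- paste(df$target_id, df$measurement_kind, sep = "|")
    for (k in unique(sort(key, method = "radix"))) {
      d <- df[key == k, , drop = FALSE]
      out <- tibble::tibble(
        target_id = d$target_id, cpd_a = d$cpd_a, cpd_b = d$cpd_b,
        smiles_a = unname(smiles_of[d$cpd_a]),
        smiles_b = unname(smiles_of[d$cpd_b]),
        core = d$core, transformation = d$transformation,
        pPot_a = unname(pot_of[d$cpd_a]), pPot_b = unname(pot_of[d$cpd_b]),
        delta = abs(unname(pot_of[d$cpd_a]) - unname(pot_of[d$cpd_b])),
        scheme = scheme
      )
      f <- sprintf("%s_%s_%s.tsv", slug(d$target_id[1]),
                   slug(d$measurement_kind[1]), artifact)
      write_tsv(out, file.path(tdir, f))
    }
  }
  for (k in unique(paste(target_sets$target_id,
                         target_sets$measurement_kind, sep = "|"))) {
    d <- target_sets[paste(target_sets$target_id,
                           target_sets$measurement_kind, sep = "|") == k, ]
    f <- sprintf("%s_%s_target_set.tsv", slug(d$target_id[1]),
                 slug(d$measurement_kind[1]))
    write_tsv(d[, c("compound_id", "canonical_smiles", "pPotency")],
              file.path(tdir, f))
  }
  write_pairs(result$mmps, "mmps", "standard")
  for (t in names(result$cliffs)) {
    write_pairs(result$cliffs[[t]], paste0("cliffs_", gsub("\\.", "p", t)),
                "standard")
  }
  write_pairs(result$recap_mmps, "recap_mmps", "recap")
  if (!is.null(result$matching) && nrow(result$matching) > 0) {
    m <- result$matching
    key <- paste(m$target_id, m$measurement_kind, sep = "|")
    for (k in unique(sort(key, method = "radix"))) {
      d <- m[key == k, , drop = FALSE]
      flat <- tibble::tibble(
        target_id = d$target_id, core_a = d$core_a, core_b = d$core_b,
        n_pairs = d$n_pairs, span_a = d$span_a, span_b = d$span_b,
        progression = d$progression, rank_correlation = d$rank_correlation,
        substituents = vapply(d$pairs, function(p) {
          paste(p$fragment, collapse = ";")
        }, ""),
        pPot_a = vapply(d$pairs, function(p) {
          paste(formatC(p$pPot_a, digits = 15, format = "g"), collapse = ";")
        }, ""),
        pPot_b = vapply(d$pairs, function(p) {
          paste(formatC(p$pPot_b, digits = 15, format = "g"), collapse = ";")
        }, "")
      )
      f <- sprintf("%s_%s_sar_transfer.tsv", slug(d$target_id[1]),
                   slug(d$measurement_kind[1]))
      write_tsv(flat, file.path(tdir, f))
    }
  }
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
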