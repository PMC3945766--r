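# Deterministic synthetic fixture generator.
#
# Fixtures emulate curated ChEMBL-style target sets: per target, analog
# series built as cores x substituents with additive pKi assignments
# (core effect + substituent effect, optional Gaussian noise), emitted as a
# compound table and an activity table in the dialect the curation module
# reads. A combinatorial oracle derives the expected MMP, cliff, matching-
# and regular-series counts directly from the plan, without running any
# fragmentation, so pipeline output can be compared against planted ground
# truth exactly.
#
# Plan contract for the oracle to be exact: within a target, substituents
# must be pairwise non-nested (no substituent a prefix-extension of another
# at the attachment atom) and cores must not be related by a size-legal
# transformation; the shipped default plans satisfy this by construction.

#' Describe one fixture target
#'
#' @param target_id,measurement_kind identifiers for the emitted records.
#' @param cores data frame with columns `name`, `smiles` (one attachment
#'   atom), `heavy` (heavy atoms excluding the attachment), `effect`
#'   (additive pKi contribution), and optionally `retro_context_heavy` /
#'   `retro_frag_extra` describing where an enabled retrosynthetic rule cuts
#'   compounds built on this core: the retro context size and the heavy
#'   atoms the core contributes to the retro fragment.
#' @param subs data frame with columns `name`, `smiles` (attachment-carrying
#'   fragment SMILES, or [H_FRAGMENT]), `heavy`, `effect`.
#' @return a `fixture_target` list.
#' @export
fixture_target <- function(target_id, measurement_kind, cores, subs) {
  cores <- tibble::as_tibble(cores)
  subs <- tibble::as_tibble(subs)
  stopifnot(all(c("name", "smiles", "heavy", "effect") %in% names(cores)),
            all(c("name", "smiles", "heavy", "effect") %in% names(subs)),
            measurement_kind %in% MEASUREMENT_KINDS)
  if (!"retro_context_heavy" %in% names(cores)) {
    cores$retro_context_heavy <- NA_real_
  }
  if (!"retro_frag_extra" %in% names(cores)) {
    cores$retro_frag_extra <- NA_real_
  }
  structure(list(target_id = target_id,
                 measurement_kind = measurement_kind,
                 cores = cores, subs = subs),
            class = "fixture_target")
}

#' Assemble a fixture plan
#'
#' @param seed integer seed; the same seed and plan give byte-identical
#'   compound and activity tables.
#' @param targets list of [fixture_target()] blocks.
#' @param noise_sd standard deviation of Gaussian noise added to each pKi
#'   (log units); 0 (the default) keeps the oracle exact.
#' @param decoys include the curation decoy battery: records violating the
#'   qualifier/confidence/relationship filters, replicate sets inside and
#'   outside the one-order-of-magnitude window, a structural-duplicate pair,
#'   a salt form, a charged form, and an unparsable structure.
#' @param cliff_thresholds potency-difference thresholds (orders of
#'   magnitude) tabulated by the oracle.
#' @return a `fixture_plan` list.
#' @export
fixture_plan <- function(seed = 1, targets = NULL, noise_sd = 0,
                         decoys = TRUE, cliff_thresholds = c(1, 2)) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (is.null(targets)) targets <- default_fixture_targets()
  structure(list(seed = as.integer(seed), targets = targets,
                 noise_sd = noise_sd, decoys = decoys,
                 cliff_thresholds = cliff_thresholds),
            class = "fixture_plan")
}

#' Default fixture targets
#'
#' Three targets emulating common medicinal-chemistry situations:
#' * `T-KIN1` (Ki): two analog series with distant scaffolds (benzene and
#'   naphthalene) sharing one substituent set — plants MMPs, cliffs at both
#'   thresholds, and one regular SAR transfer series.
#' * `T-PROT2` (Ki): one amide-linked series (acyl naphthalen-2-ylamides) —
#'   plants MMPs that are also retrosynthetic (amide-rule) MMPs.
#' * `T-GPCR3` (IC50): one small benzene series — exercises the separate
#'   handling of the IC50 measurement kind.
#'
#' Substituent effects span more than two orders of magnitude so the planted
#' series qualify for SAR transfer, with pairwise gaps placing some compound
#' pairs above and some below each cliff threshold.
#' @return list of [fixture_target()] blocks.
#' @export
default_fixture_targets <- function() {
  list(
    fixture_target(
      "T-KIN1", "Ki",
      cores = tibble::tibble(
        name = c("phenyl", "naphthyl"),
        smiles = c("[*]c1ccccc1", "[*]c1ccc2ccccc2c1"),
        heavy = c(6, 10),
        effect = c(4.5, 5.2)
      ),
      subs = tibble::tibble(
        name = c("H", "fluoro", "chloro", "methyl", "amino"),
        smiles = c(H_FRAGMENT, "[*]F", "[*]Cl", "[*]C", "[*]N"),
        heavy = c(0, 1, 1, 1, 1),
        effect = c(0, 0.5, 1.2, 2.3, 3.1)
      )
    ),
    fixture_target(
      "T-PROT2", "Ki",
      cores = tibble::tibble(
        name = "acylnaphthylamide",
        smiles = "[*]C(=O)Nc1ccc2ccccc2c1",
        heavy = 13,
        effect = 5.0,
        retro_context_heavy = 11,  # [*]Nc1ccc2ccccc2c1
        retro_frag_extra = 2       # the C=O the core lends the acyl fragment
      ),
      subs = tibble::tibble(
        name = c("methyl", "ethyl", "propyl", "isopropyl"),
        smiles = c("[*]C", "[*]CC", "[*]CCC", "[*]C(C)C"),
        heavy = c(1, 2, 3, 3),
        effect = c(0, 0.9, 2.1, 2.8)
      )
    ),
    fixture_target(
      "T-GPCR3", "IC50",
      cores = tibble::tibble(
        name = "phenyl", smiles = "[*]c1ccccc1", heavy = 6, effect = 5.5
      ),
      subs = tibble::tibble(
        name = c("H", "chloro", "amino"),
        smiles = c(H_FRAGMENT, "[*]Cl", "[*]N"),
        heavy = c(0, 1, 1),
        effect = c(0, 1.1, 2.4)
      )
    )
  )
}

activity_row <- function(compound_id, target_id, kind, value_nM,
                         relation = "=", confidence = 9, type = "D") {
  tibble::tibble(compound_id = compound_id, target_id = target_id,
                 measurement_kind = kind, relation = relation,
                 value_nM = value_nM, confidence_score = confidence,
                 relationship_type = type)
}

# Fixed curation decoy battery on targets T-QC (Ki) and T-QC (IC50).
# Retained after curation: QC01 (desalted ethanol), QC02 (neutralized
# acetate), QC08A+QC08B (merged chlorophenol duplicate), QC09 (cyclohexane
# replicates within one OoM) for Ki; QC10 (thiophene) for IC50. The
# structures are chosen so no two retained members share a size-legal
# decomposition, hence the QC targets contribute zero MMPs.
decoy_block <- function() {
  compounds <- tibble::tibble(
    compound_id = c("QC01", "QC02", "QC03", "QC04", "QC05", "QC06", "QC07",
                    "QC08A", "QC08B", "QC09", "QC10", "QC11"),
    smiles = c("CCO.[Na+].[Cl-]", "CC(=O)[O-]", "C1CC", "Oc1ccccc1",
               "Cc1ccncc1", "OCCCC", "CCCCCCCC", "Oc1ccc(Cl)cc1",
               "Oc1ccc(Cl)cc1", "C1CCCCC1", "c1ccsc1", "CCCC")
  )
  activities <- dplyr::bind_rows(
    activity_row("QC01", "T-QC", "Ki", 100),
    activity_row("QC02", "T-QC", "Ki", 50),
    activity_row("QC03", "T-QC", "Ki", 10),                      # no structure
    activity_row("QC04", "T-QC", "Ki", 1000, relation = ">"),    # qualifier
    activity_row("QC05", "T-QC", "Ki", 20, confidence = 8),      # confidence
    activity_row("QC06", "T-QC", "Ki", 30, type = "B"),          # relationship
    activity_row("QC07", "T-QC", "Ki", c(1, 1000)),              # OoM discard
    activity_row(c("QC08A", "QC08B"), "T-QC", "Ki", c(10, 20)),  # dup merge
    activity_row("QC09", "T-QC", "Ki", c(10, 100)),              # replicates
    activity_row("QC10", "T-QC", "IC50", 50),
    activity_row("QC11", "T-QC", "Ki", -5),                      # nonpositive
    activity_row("QC04", "T-QC", "EC50", 10),                    # kind
    activity_row("QC04", "T-QC", "Ki", NA_real_)                 # missing
  )
  expected <- list(
    filter_drops = c(missing_value = 1L, relation = 1L, confidence = 1L,
                     relationship = 1L, kind = 1L, nonpositive = 1L),
    n_no_structure = 1L, n_oom_discarded = 1L, n_duplicates_merged = 1L,
    retained = tibble::tibble(
      target_id = c("T-QC", "T-QC"),
      measurement_kind = c("Ki", "IC50"),
      n_members = c(4L, 1L)
    )
  )
  list(compounds = compounds, activities = activities, expected = expected)
}

#' Generate a fixture data set
#'
#' Builds every core x substituent compound by reattaching the substituent
#' at the core's attachment point, verifies heavy-atom bookkeeping against
#' the plan, assigns potencies from the additive model, and emits the
#' compound and activity tables together with the ground-truth manifest from
#' [fixture_manifest()].
#'
#' @param plan a [fixture_plan()].
#' @return list with elements `compounds` (tibble `compound_id`, `smiles`),
#'   `activities` (curation-dialect activity tibble), `manifest`, `plan`.
#' @export
generate_fixture <- function(plan = fixture_plan()) {
  stopifnot(inherits(plan, "fixture_plan"))
  set.seed(plan$seed)
  comp_rows <- list()
  act_rows <- list()
  for (tgt in plan$targets) {
    grid <- expand.grid(ci = seq_len(nrow(tgt$cores)),
                        si = seq_len(nrow(tgt$subs)))
    core <- tgt$cores[grid$ci, ]
    sub <- tgt$subs[grid$si, ]
    smiles <- chem_reassemble(core$smiles, sub$smiles)
    bad <- is.na(smiles)
    if (any(bad)) {
      k <- which(bad)[1]
      stop("invalid scaffold/substituent combination: core '",
           core$name[k], "' + substituent '", sub$name[k], "'",
           call. = FALSE)
    }
    ids <- sprintf("%s-%s-%s", tgt$target_id, core$name, sub$name)
    check <- chem_standardize(smiles)
    mismatch <- check$heavy_atoms != core$heavy + sub$heavy
    if (any(mismatch)) {
      k <- which(mismatch)[1]
      stop("plan heavy-atom counts disagree with structure for '",
           ids[k], "'", call. = FALSE)
    }
    pki <- core$effect + sub$effect
    if (plan$noise_sd > 0) {
      pki <- pki + stats::rnorm(length(pki), sd = plan$noise_sd)
    }
    comp_rows[[length(comp_rows) + 1]] <-
      tibble::tibble(compound_id = ids, smiles = smiles)
    act_rows[[length(act_rows) + 1]] <-
      activity_row(ids, tgt$target_id, tgt$measurement_kind,
                   10^(9 - pki))
  }
  if (isTRUE(plan$decoys)) {
    dec <- decoy_block()
    comp_rows[[length(comp_rows) + 1]] <- dec$compounds
    act_rows[[length(act_rows) + 1]] <- dec$activities
  }
  list(compounds = dplyr::bind_rows(comp_rows),
       activities = dplyr::bind_rows(act_rows),
       manifest = fixture_manifest(plan),
       plan = plan)
}

# inline size legality: deliberately plain arithmetic, independent of the
# pipeline's apply_size_rules()
.legal <- function(core, fa, fb) {
  core >= 2 * fa & core >= 2 * fb & abs(fa - fb) <= 8 & pmax(fa, fb) <= 13
}

#' Combinatorial ground-truth manifest for a fixture plan
#'
#' Derives, per target and per measurement kind, the expected number of
#' pair-level MMPs, MMP compounds, cliffs at each threshold, matching and
#' regular SAR transfer series, and retrosynthetic MMPs — purely from the
#' plan's core/substituent sizes and additive effects, without running any
#' fragmentation. Cliff and series counts are exact for noise-free plans
#' (`exact` element); pair topology counts hold regardless of noise.
#'
#' @param plan a [fixture_plan()].
#' @return list with `targets` (per-target tibble), `by_kind` (aggregated
#'   tibble), `decoys` (expected curation drops, when planted), and `exact`.
#' @export
fixture_manifest <- function(plan) {
  thr <- plan$cliff_thresholds
  rows <- lapply(plan$targets, function(tgt) {
    nc <- nrow(tgt$cores)
    ns <- nrow(tgt$subs)
    pair_idx <- if (ns >= 2) utils::combn(ns, 2) else
      matrix(integer(0), nrow = 2)
    mmp <- 0L
    recap <- 0L
    mmp_cpds <- character(0)
    recap_cpds <- character(0)
    cliff_pairs <- stats::setNames(integer(length(thr)), as.character(thr))
    cliff_cpds <- stats::setNames(vector("list", length(thr)),
                                  as.character(thr))
    for (t in as.character(thr)) cliff_cpds[[t]] <- character(0)
    for (ci in seq_len(nc)) {
      ch <- tgt$cores$heavy[ci]
      for (k in seq_len(ncol(pair_idx))) {
        i <- pair_idx[1, k]; j <- pair_idx[2, k]
        hi <- tgt$subs$heavy[i]; hj <- tgt$subs$heavy[j]
        id_i <- sprintf("%s-%s-%s", tgt$target_id, tgt$cores$name[ci],
                        tgt$subs$name[i])
        id_j <- sprintf("%s-%s-%s", tgt$target_id, tgt$cores$name[ci],
                        tgt$subs$name[j])
        if (.legal(ch, hi, hj)) {
          mmp <- mmp + 1L
          mmp_cpds <- c(mmp_cpds, id_i, id_j)
          d <- abs(tgt$subs$effect[i] - tgt$subs$effect[j])
          for (t in seq_along(thr)) {
            if (d >= thr[t]) {
              tc <- as.character(thr[t])
              cliff_pairs[[tc]] <- cliff_pairs[[tc]] + 1L
              cliff_cpds[[tc]] <- c(cliff_cpds[[tc]], id_i, id_j)
            }
          }
        }
        rc <- tgt$cores$retro_context_heavy[ci]
        re <- tgt$cores$retro_frag_extra[ci]
        if (!is.na(rc) && .legal(rc, hi + re, hj + re)) {
          recap <- recap + 1L
          recap_cpds <- c(recap_cpds, id_i, id_j)
        }
      }
    }
    # cross-core pairs sharing a substituent: the shared substituent is the
    # context and the two cores are the exchanged fragments
    if (nc >= 2) {
      core_pairs <- utils::combn(nc, 2)
      for (k in seq_len(ncol(core_pairs))) {
        a <- core_pairs[1, k]; b <- core_pairs[2, k]
        for (si in seq_len(ns)) {
          sh <- tgt$subs$heavy[si]
          if (sh > 0 && .legal(sh, tgt$cores$heavy[a], tgt$cores$heavy[b])) {
            mmp <- mmp + 1L
            ids <- sprintf("%s-%s-%s", tgt$target_id,
                           tgt$cores$name[c(a, b)], tgt$subs$name[si])
            mmp_cpds <- c(mmp_cpds, ids)
            d <- abs(tgt$cores$effect[a] - tgt$cores$effect[b])
            for (t in seq_along(thr)) {
              if (d >= thr[t]) {
                tc <- as.character(thr[t])
                cliff_pairs[[tc]] <- cliff_pairs[[tc]] + 1L
                cliff_cpds[[tc]] <- c(cliff_cpds[[tc]], ids)
              }
            }
          }
        }
      }
    }
    # matching / regular series: core pairs whose mutually size-legal shared
    # substituents number >= 3 and span >= 2 log units
    matching <- 0L
    regular <- 0L
    if (nc >= 2) {
      core_pairs <- utils::combn(nc, 2)
      for (k in seq_len(ncol(core_pairs))) {
        a <- core_pairs[1, k]; b <- core_pairs[2, k]
        legal_member <- tgt$subs$heavy <= 13 &
          tgt$cores$heavy[a] >= 2 * tgt$subs$heavy &
          tgt$cores$heavy[b] >= 2 * tgt$subs$heavy
        eff <- tgt$subs$effect[legal_member]
        if (sum(legal_member) >= 3 && (max(eff) - min(eff)) >= 2) {
          matching <- matching + 1L
          if (!anyDuplicated(eff)) regular <- regular + 1L
        }
      }
    }
    out <- tibble::tibble(
      target_id = tgt$target_id,
      measurement_kind = tgt$measurement_kind,
      n_compounds = nc * ns,
      mmp_pairs = mmp,
      mmp_compounds = length(unique(mmp_cpds)),
      recap_pairs = recap,
      recap_compounds = length(unique(recap_cpds)),
      matching_series = matching,
      regular_series = regular
    )
    for (t in as.character(thr)) {
      out[[paste0("cliff_pairs_", t)]] <- cliff_pairs[[t]]
      out[[paste0("cliff_compounds_", t)]] <- length(unique(cliff_cpds[[t]]))
    }
    out
  })
  targets <- dplyr::bind_rows(rows)
  if (isTRUE(plan$decoys)) {
    dec <- decoy_block()$expected
    qc <- dec$retained
    extra <- tibble::tibble(
      target_id = qc$target_id, measurement_kind = qc$measurement_kind,
      n_compounds = qc$n_members, mmp_pairs = 0L, mmp_compounds = 0L,
      recap_pairs = 0L, recap_compounds = 0L, matching_series = 0L,
      regular_series = 0L
    )
    for (t in as.character(thr)) {
      extra[[paste0("cliff_pairs_", t)]] <- 0L
      extra[[paste0("cliff_compounds_", t)]] <- 0L
    }
    targets <- dplyr::bind_rows(targets, extra)
  }
  grp <- dplyr::group_by(targets, .data$measurement_kind)
  by_kind <- dplyr::summarise(
    grp,
    n_targets = dplyr::n(),
    n_compounds = sum(.data$n_compounds),
    mmps = sum(.data$mmp_pairs),
    targets_with_mmps = sum(.data$mmp_pairs > 0),
    mmp_compounds = sum(.data$mmp_compounds),
    recap_mmps = sum(.data$recap_pairs),
    targets_with_recap = sum(.data$recap_pairs > 0),
    recap_compounds = sum(.data$recap_compounds),
    matching_series = sum(.data$matching_series),
    regular_series = sum(.data$regular_series),
    .groups = "drop"
  )
  for (t in as.character(thr)) {
    cp <- paste0("cliff_pairs_", t)
    cc <- paste0("cliff_compounds_", t)
    agg_p <- tapply(targets[[cp]], targets$measurement_kind, sum)
    agg_t <- tapply(targets[[cp]] > 0, targets$measurement_kind, sum)
    agg_c <- tapply(targets[[cc]], targets$measurement_kind, sum)
    by_kind[[cp]] <- as.integer(agg_p[by_kind$measurement_kind])
    by_kind[[paste0("targets_with_cliffs_", t)]] <-
      as.integer(agg_t[by_kind$measurement_kind])
    by_kind[[cc]] <- as.integer(agg_c[by_kind$measurement_kind])
  }
  list(
    targets = targets,
    by_kind = by_kind,
    decoys = if (isTRUE(plan$decoys)) decoy_block()$expected else NULL,
    exact = plan$noise_sd == 0
  )
}
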