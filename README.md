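# mmpairs

Matched-molecular-pair (MMP) data sets for computer-aided medicinal
chemistry, generated from compound–activity tables.

An MMP is a pair of compounds distinguished only by a structural
modification at a single site — the exchange of one substructure for
another, the *chemical transformation* `frag_left >> frag_right`, at a
shared *core*. Because the context is held fixed, MMPs attribute potency
differences to well-defined chemical changes. From curated
high-confidence Ki/IC50 data this package derives, per target and
measurement kind:

* **size-restricted MMPs** — systematic single-cut fragmentation of all
  exocyclic single bonds (with hydrogen expansion), indexed by canonical
  core in the Hussain–Rea key–value style; transformations limited to
  core ≥ 2 × fragment, fragment size difference ≤ 8 and fragment size
  ≤ 13 heavy atoms;
* **MMP-cliffs** — MMPs with |ΔpPotency| ≥ 2 orders of magnitude
  (1 OoM as the relaxed criterion), pPotency = 9 − log10(value in nM);
* **RECAP-MMPs** — MMPs whose fragmentation is restricted to bonds
  matching an editable set of retrosynthetic SMARTS rules (amide, ester,
  biaryl, ...), so transformations stay synthetically interpretable;
* **target-based SAR transfer series** — pairs of analog series with
  different cores, ≥ 3 corresponding substituents and ≥ 2 OoM potency
  span, classified by potency-progression quality (regular /
  approximate) via Spearman rank correlation.

Curation follows the high-confidence recipe: relation `"="` only,
target confidence score 9, relationship type `"D"`, Ki and IC50 handled
as separate target sets, geometric-mean replicate aggregation within one
order of magnitude (otherwise the compound is discarded), salt stripping
and charge neutralization before canonicalization.

The package is for cheminformaticians and computational medicinal
chemists who want reproducible MMP/activity-cliff/SAR-transfer data sets
from their own or public activity tables — plus a deterministic synthetic
fixture generator with a combinatorial ground-truth oracle so the whole
pipeline is verifiable without downloading a database.

## Worked example

```r
library(mmpairs)

# synthetic study conditions: 3 planted targets + curation decoys
fx  <- generate_fixture(fixture_plan(seed = 1))
res <- run_mmp_pipeline(fx$compounds, fx$activities, mmp_config(seed = 1))

r <- res$report$by_kind$Ki
sprintf("Ki: %d MMPs | cliffs 2 OoM: %d (%.1f%%) | RECAP-MMPs: %d | transfer series: %d (regular %d)",
        r$mmps, r$cliffs$oom_2$mmp_cliffs, r$cliffs$oom_2$pct_of_mmps,
        r$recap_mmps, r$sar_transfer_series, r$sar_transfer_series_regular)
#> "Ki: 26 MMPs | cliffs 2 OoM: 8 (30.8%) | RECAP-MMPs: 6 | transfer series: 1 (regular 1)"

head(res$cliffs[["2"]][, c("cpd_low", "cpd_high", "pPot_low", "pPot_high",
                           "delta", "transformation")], 3)
#>             cpd_low               cpd_high pPot_low pPot_high delta transformation
#> 1  T-GPCR3-phenyl-H   T-GPCR3-phenyl-amino      5.5       7.9   2.4     *N>>[*][H]
#> 2 T-KIN1-naphthyl-H  T-KIN1-naphthyl-amino      5.2       8.3   3.1     *N>>[*][H]
#> 3 T-KIN1-naphthyl-H T-KIN1-naphthyl-methyl      5.2       7.5   2.3     *C>>[*][H]
```

The 26 Ki MMPs are every size-legal substituent pair on the two planted
scaffold series plus the amide series; the 8 cliffs at 2 OoM are exactly
the pairs whose planted substituent effects differ by ≥ 2 log units
(e.g. unsubstituted naphthalene at pKi 5.2 vs. the amino analog at 8.3);
and the one transfer series is the benzene/naphthalene series pair, whose
shared substituents progress in identical rank order (`regular`,
Spearman ρ = 1) because potency effects are additive:

```r
res$matching[, c("core_a", "core_b", "n_pairs", "span_a", "progression")]
#>            core_a    core_b n_pairs span_a progression
#> 1 *c1ccc2ccccc2c1 *c1ccccc1       5    3.1     regular
```

Individual stages are exported. The classic toluene/ethylbenzene pair:

```r
mol <- standardize_molecules(tibble::tibble(
  compound_id = c("tol", "eb"), smiles = c("Cc1ccccc1", "CCc1ccccc1")))
assemble_mmps(build_fragment_index(enumerate_cuts(mol)))
#>   cpd_a cpd_b       core core_heavy frag_a frag_b ... transformation
#> 1    eb   tol *Cc1ccccc1          7     *C [*][H] ...     *C>>[*][H]
```

One canonical MMP per compound pair is reported, chosen over the largest
shared context (here H → methyl at the 7-atom benzyl core rather than
methyl → ethyl at phenyl); `mmp_config(exhaustive = TRUE)` keeps every
admissible transformation instead.

A command-line front end with subcommands (`fixtures`, `curate`, `mmp`,
`cliffs`, `recap-mmp`, `sar-transfer`, `report`) lives at
`system.file("cli", "mmpairs.R", package = "mmpairs")`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mmpairs.R", package = "mmpairs"))')
Rscript "$CLI" fixtures --seed 1 --out fixture
Rscript "$CLI" report --compounds fixture/compounds.tsv \
        --activities fixture/activities.tsv --out run
```

Per-target TSVs (separately for Ki and IC50) and a JSON run report with
MMP / cliff / SAR-transfer / RECAP counters are written beneath the
output directory. See the vignette (`vignettes/mmp-data-generation.Rmd`)
for the full method description and design rationale.

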