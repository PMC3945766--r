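---
title: "Generating matched-molecular-pair data sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating matched-molecular-pair data sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The objects this package computes

A *matched molecular pair* (MMP) is a pair of compounds distinguished only
by a structural modification at a single site: the exchange of one
substructure for another, called a *chemical transformation* and written
`frag_left >> frag_right`. Because the unchanged part (the *core*) is held
fixed, an MMP attributes a property difference — here, a potency
difference — to one well-defined chemical change. On top of MMPs the
package derives three data structures:

* **MMP-cliffs**: MMPs whose partners differ in potency by at least a
  threshold number of orders of magnitude (OoM). The default threshold is
  2 OoM, with 1 OoM as a relaxed variant; MMP formation itself serves as
  the similarity criterion, so no fingerprint similarity is involved.
* **Retrosynthetic (RECAP) MMPs**: MMPs whose defining fragmentation is
  restricted to bonds matching retrosynthetic reaction rules (amide,
  ester, biaryl, ...), so that the transformation corresponds to a change
  a chemist could plausibly make in one synthetic step.
* **Target-based SAR transfer series**: pairs of analog series on the
  same target with *different* cores but *corresponding* substituents,
  whose potencies progress in the same (or nearly the same) rank order —
  evidence that a SAR learned on one scaffold transfers to another.

## Activity data curation

Input activity records carry a compound identifier, target identifier,
measurement kind (Ki or IC50), relation qualifier, potency in nM, a target
confidence score and a target relationship code. Curation retains only
records with an exact measurement (relation `"="`; approximate
measurements `>`, `<`, `~` and records without a value are discarded), the
highest target confidence score (9), and a direct target relationship
(type `"D"`). Ki and IC50 measurements are never mixed: each (target,
kind) combination forms its own *target set*, because assay-dependent IC50
values are not directly comparable with binding constants.

Potency is expressed as pPotency = 9 − log10(value in nM), i.e. the
negative decadic logarithm of the molar potency (a 1 nM compound has
pPotency 9). For compounds measured repeatedly against the same target the
final annotation is the geometric mean, **provided** all replicates fall
within one order of magnitude (max/min ≤ 10); otherwise the compound is
discarded from that target set. The window is read as an inclusive bound —
a replicate pair spanning exactly 10× still aggregates — since the
boundary convention is not otherwise fixed; the choice only matters for
ratios exactly equal to 10.

Structures are standardized before curation: the largest organic covalent
component is kept (salt/solvent stripping; ties broken by the
lexicographically smaller canonical SMILES so output is deterministic),
charges are neutralized wherever a proton can be added or removed without
exceeding standard valence (internally compensated charges such as nitro
groups are left intact), and the canonical SMILES is computed with RDKit.
Stereochemistry is preserved as given — neither enumerated nor stripped.
Two identifiers with the same canonical SMILES in the same target set are
merged *before* replicate aggregation, so a structure can never enter a
target set twice under different identifiers. Canonicalization is RDKit's
algorithm; agreement with other toolkits' canonical strings is explicitly
not a contract, which is why all cross-checks in this package compare
structures after round-tripping through the same canonicalizer.

## Fragmentation and the fragment index

Standard MMP generation fragments every *exocyclic single bond* — an
acyclic single bond between two heavy (non-hydrogen) atoms. Ring bonds,
bonds to hydrogen and multiple bonds are never cut. Each cut produces a
(core, fragment) pair in both orientations, each side serving once as the
exchanged fragment, with a single unlabeled attachment atom (`*`) marking
the cut position. The attachment atom is never counted as a heavy atom.

Two invariants hold for every cut and are enforced by tests and by an
audit pass: reattaching fragment to core reproduces the parent canonical
SMILES, and core plus fragment heavy atoms sum to the parent count.

*Hydrogen expansion* (on by default) additionally emits, for every
symmetry-distinct hydrogen-bearing position, a cut whose core is the whole
molecule with an attachment point at that position and whose fragment is
the hydrogen pseudo-fragment (`[*][H]`, 0 heavy atoms). Without it,
transformations that *add* a substituent to an unsubstituted position —
including the addition of an entire substituted ring, the largest
permitted transformation class — would be unreachable. Symmetric positions
are deduplicated by the canonical core SMILES.

Cuts from all members of a target set are indexed by canonical core
SMILES (the key-value idea of Hussain and Rea): compounds sharing a key
share a decomposition, so candidate MMPs are read off per key instead of
by all-pairs structure comparison. Index entries are sorted under C
collation; every string ordering in the package (pair orientation,
transformation direction, tie-breaks) uses C collation via radix sorting
so that results do not depend on the session locale.

## Size restrictions and canonical pair selection

Transformations are limited to meaningful chemical substitutions by three
rules, applied to every candidate: the core must be at least **twice** the
size of each exchanged fragment; the two fragments may differ by at most
**8** heavy atoms; and no fragment may exceed **13** heavy atoms. All
three parameters are configurable but default to this reference
parameterization. The hydrogen pseudo-fragment (0 atoms) trivially passes
the core rule, and the ≤ 8 difference rule then caps hydrogen-to-fragment
additions at 8 heavy atoms.

One compound pair can satisfy the MMP definition through several
decompositions (e.g. H → methyl at a benzylic core is the same pair as
methyl → ethyl at the phenyl core). Pair-level statistics count each
unordered pair once; the canonical representative minimizes, in order, the
larger fragment's size, the total fragment size, and the core string under
C collation. This prefers the transformation with the largest shared
context — the minimal single-site change — which matches the intuition
behind the MMP definition. Because the counting unit (pairs vs.
pair-transformations) is genuinely ambiguous in published statistics, the
exhaustive per-transformation list remains available via
`mmp_config(exhaustive = TRUE)`.

Cliff detection then keeps the MMPs with |ΔpPotency| ≥ threshold,
recording orientation from the less to the more potent compound. Cliffs at
2 OoM are by construction a subset of cliffs at 1 OoM; the test suite
asserts this nesting on every run.

## Retrosynthetic rules

RECAP-mode fragmentation replaces "every exocyclic single bond" with "every
bond matching an enabled retrosynthetic rule". Rules are SMARTS patterns
with two mapped atoms (`:1`, `:2`) defining the cleavable bond, shipped as
an editable TSV (`inst/extdata/recap_rules.tsv`) and overridable per run.
The default file implements the classic RECAP bond classes — amide, ester,
amine, urea, ether, olefin, quaternary nitrogen, aromatic N–aliphatic C,
lactam N–aliphatic C, aromatic C–aromatic C (biaryl), sulfonamide — plus
two disabled extension slots. The exact 13-rule set used in earlier
retrosynthetic MMP work is not enumerated in the accessible literature, so
this file is a documented best reconstruction and deliberately
user-editable; rule identity does not affect any package invariant, only
which bonds qualify.

Matched bonds must be acyclic at application time; a bond matching several
rules is reported once with all rule identifiers. Hydrogen expansion is
*not* applied in retro mode, since a retrosynthetic cut requires a
reaction-derived bond between two heavy atoms. The olefin rule cleaves a
double bond and is disabled by default because the single-bond reassembly
contract does not cover it; when enabled, cutting and reassembly preserve
the native bond order (this path is exercised by a dedicated test). On
single-bond rules, retro cuts are a strict subset of the standard cut set,
so RECAP-MMP counts can never exceed standard MMP counts on the same
target set — mirroring the qualitative published observation that
retrosynthetic rules reduce MMP numbers substantially.

## SAR transfer series

Analog series are read directly off the fragment index: one series per
core, one member per substituent, where each (core, substituent)
decomposition must itself satisfy the per-cut size rules (core ≥ 2 ×
substituent, substituent ≤ 13). A compound contributes to every core it
exhibits. Two series on the same target with *different* cores form a
*matching series* when they share at least 3 substituent keys and the
matched pairs span at least 2 OoM in both series. The span is computed
over the matched pairs only — the matched sub-series is the reported
object — rather than over all series members; with whole-series spans,
an unmatched outlier member could qualify a pair of series whose matched
portion is flat.

Progression is classified by the Spearman rank correlation between the
paired potencies: *regular* when the rank orders correspond strictly
(correlation exactly 1 with no ties), *approximate* when the correlation
reaches 0.7 without being regular, otherwise unclassified. The 0.7
operationalization is a design choice — "approximate potency progression"
has no closed published definition — and is exposed as
`mmp_config(approx_threshold = )`. Potency ties (within 1e-9 log units)
break ranking deterministically by substituent SMILES but always
disqualify the regular class, because strict rank correspondence is
undefined under ties. By construction regular ⊆ transfer ⊆ matching,
asserted on every run.

## The synthetic fixture generator and its oracle

`generate_fixture()` emulates curated bioactivity target sets without any
database access: per target, compounds are built as cores × substituents
with additive pKi assignments (core effect + substituent effect, optional
seeded Gaussian noise), emitted as compound and activity tables in exactly
the dialect the curation stage reads, alongside a decoy battery of records
violating each curation filter. The default plan holds three targets: two
distant scaffolds (benzene, naphthalene) sharing one substituent set —
planting MMPs, cliffs on both sides of each threshold, and one regular
transfer series; an amide-linked acyl naphthylamide series whose MMPs are
also amide-rule RECAP-MMPs; and a small IC50 series exercising measurement
kind separation. Substituent effects (0, 0.5, 1.2, 2.3, 3.1 log units on
the kinase target) were chosen once so that the planted series spans more
than 2 OoM and pairwise gaps fall on both sides of both cliff thresholds;
noise-free generation is the default so expected counts are exact.

A combinatorial oracle (`fixture_manifest()`) derives expected counts
directly from the plan — C(S, 2) size-legal pairs per core, cliff pairs
from pairwise effect differences, matching/regular series from shared
size-legal substituents — using inline arithmetic, never the fragmentation
machinery it validates. For the oracle to be exact the plan must avoid
substituents that are attachment-prefixes of one another and cores related
by a size-legal transformation; otherwise homologous "ladder" series and
cross-core pairs appear that the combinatorial count does not model. The
shipped default plans satisfy this by construction (the decoy structures
were likewise chosen so that no two retained members share a size-legal
decomposition; an earlier draft used two homologous alcohols, which the
pipeline correctly — and the oracle not at all — counted as an MMP).

What the fixtures deliberately do **not** emulate: real medicinal-chemistry
structural diversity, multi-site substitutions, stereochemistry,
tautomerism, assay noise structure, or the heavy-tailed target-set size
distribution of curated databases. Passing the planted-recovery tests
therefore demonstrates correctness of the combinatorial machinery on
well-posed inputs, not robustness to the full messiness of real data; the
reassembly, nesting, subset and audit properties, which hold for arbitrary
molecules, are tested on randomized structure sets as well.

## Numerical and engineering choices

* **Chemistry backend.** SMILES parsing, standardization, fragmentation
  and SMARTS matching run in RDKit through a bundled Python helper
  invoked per *batch* (one process per vectorized call, memoised per
  molecule within a session). The R side owns all pipeline logic. The
  interpreter is located via `options(mmpairs.python =)` or
  `MMPAIRS_PYTHON`, defaulting to `python` on the PATH.
* **Determinism.** All orderings use C collation; TSVs are written with
  fixed `\n` endings and 15 significant digits; two runs with identical
  inputs, configuration and seed are byte-identical (tested).
* **Degenerate inputs.** Unparsable SMILES are record-level failures that
  are logged and skipped, never batch aborts; empty target sets produce
  empty indexes, zero-count reports and valid (empty) outputs.
* **Problem sizes.** The shipped verification suite runs the default
  fixture (29 compounds, 5 target sets) end to end and 20 randomized
  target sets of up to ~40 molecules for the brute-force equivalence
  check — sizes at which the all-pairs oracle is exact and fast. The
  pipeline itself is linear per index key and has no intrinsic scale
  limit; full-database runs are supported as a scalable mode but are not
  part of the test envelope.

## Known limitations

* Single-cut MMPs only: multi-attachment (double/triple-cut) cores and
  transformation-level analytics across targets are out of scope.
* Multi-target SAR transfer (one series, two targets) is not implemented;
  the package identifies target-based transfer between two series on one
  target.
* The neutralization rules are generic (protonate/deprotonate where
  valence permits); they do not reproduce any specific commercial
  standardizer, and canonical SMILES are RDKit-canonical, not comparable
  byte-for-byte with OpenEye/MOE output.
* The shipped retrosynthetic rule set is a reconstruction; users wanting
  a specific published rule set should supply their own SMARTS file.
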