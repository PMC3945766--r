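Package: mmpairs
Title: Matched Molecular Pairs, Activity Cliffs, and SAR Transfer Series
    from Curated Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates matched-molecular-pair (MMP) data sets from
    compound-activity tables: curation of high-confidence Ki/IC50 records
    with geometric-mean replicate aggregation, size-restricted MMP
    generation by systematic single-cut fragmentation of exocyclic single
    bonds with a core-keyed fragment index, MMP activity-cliff detection at
    configurable potency-difference thresholds, retrosynthetic (RECAP-rule)
    MMP generation, and identification of target-based SAR transfer series
    with potency-progression classification. Includes a deterministic
    synthetic fixture generator with a combinatorial ground-truth oracle so
    every stage can be verified without a database download. Chemistry
    primitives (SMILES standardization, fragmentation, SMARTS bond typing)
    are delegated to RDKit through a bundled Python helper.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit available as an importable
    module; the interpreter is located via option 'mmpairs.python' or the
    MMPAIRS_PYTHON environment variable (default "python").
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
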