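# Shared fixtures, computed lazily once per test run. The default fixture
# plan is noise-free, so the combinatorial manifest is exact and any seed
# yields the same tables.

.shared <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (is.null(.shared$fx)) {
    .shared$fx <- generate_fixture(fixture_plan(seed = 101))
  }
  .shared$fx
}

shared_pipeline <- function() {
  if (is.null(.shared$res)) {
    fx <- shared_fixture()
    .shared$res <- run_mmp_pipeline(fx$compounds, fx$activities,
                                    mmp_config(seed = 101))
  }
  .shared$res
}

shared_molecules <- function() {
  if (is.null(.shared$mol)) {
    .shared$mol <- standardize_molecules(shared_fixture()$compounds)
  }
  .shared$mol
}

# a random small target set (<= 40 molecules) drawn from fixed core and
# substituent pools; used where brute force is the oracle, so the draws do
# not need to respect the combinatorial-manifest plan contract
rand_target_molecules <- function(seed) {
  cores <- c("[*]c1ccccc1", "[*]c1ccc2ccccc2c1", "[*]Cc1ccccc1",
             "[*]c1ccccn1", "[*]C1CCCCC1", "[*]C(=O)Nc1ccccc1",
             "[*]Oc1ccccc1", "[*]c1ccco1")
  subs <- c(H_FRAGMENT, "[*]F", "[*]Cl", "[*]Br", "[*]C", "[*]CC",
            "[*]CCC", "[*]N", "[*]O", "[*]OC", "[*]C(F)(F)F", "[*]C#N",
            "[*]C(C)C", "[*]N(C)C")
  set.seed(seed)
  co <- sample(cores, sample(2:3, 1))
  su <- sample(subs, sample(4:8, 1))
  grid <- expand.grid(core = co, sub = su, stringsAsFactors = FALSE)
  smiles <- chem_reassemble_public(grid$core, grid$sub)
  stopifnot(!anyNA(smiles))
  ids <- sprintf("R%02d-%03d", seed %% 100, seq_along(smiles))
  mols <- standardize_molecules(
    tibble::tibble(compound_id = ids, smiles = smiles))
  # duplicated structures would make pair identity ambiguous; drop them
  mols[!duplicated(mols$canonical_smiles), , drop = FALSE]
}

# reach the internal batched reassembly helper without exporting it
chem_reassemble_public <- function(core, fragment) {
  getFromNamespace("chem_reassemble", "mmpairs")(core, fragment)
}
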