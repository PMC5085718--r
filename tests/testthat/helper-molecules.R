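# Shared molecule fixtures, parsed once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_mols <- function() {
  if (is.null(.fixture_env$mols)) {
    smiles <- c(methane = "C", ethanol = "CCO", benzene = "c1ccccc1",
                toluene = "Cc1ccccc1", anisole = "c1ccccc1OC",
                acetic = "CC(=O)O", glycine = "NCC(=O)O",
                trimethylamine = "CN(C)C", ethylbenzene = "CCc1ccccc1",
                dmae = "CCOCC", pdimethoxy = "c1cc(OC)ccc1OC",
                naphthalene = "c1ccc2ccccc2c1",
                tbutylbenzene = "CC(C)(C)c1ccccc1",
                chloromethane = "CCl", carbontet = "ClC(Cl)(Cl)Cl")
    mols <- parse_smiles_set(unname(smiles), names(smiles))
    names(mols) <- vapply(mols, function(m) m$mol_id, "")
    .fixture_env$mols <- mols
  }
  .fixture_env$mols
}

fixture_mol <- function(name) fixture_mols()[[name]]

# small toy library shared across tests (parsing is the slow part)
fixture_library <- function(n = 40L, seed = 7L) {
  key <- paste0("lib", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    lib <- make_toy_library(n, seed = seed)
    lib$mols <- parse_smiles_set(lib$smiles$smiles, lib$smiles$mol_id)
    .fixture_env[[key]] <- lib
  }
  .fixture_env[[key]]
}
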