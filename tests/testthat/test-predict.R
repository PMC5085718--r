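# small fitted bundles for reactions III and IV, trained once per run on
# the shared fixture library with a reduced grid (chi arm, three
# classifiers) -- prediction mechanics, not search breadth, is under test
fixture_bundles <- function() {
  if (!is.null(.fixture_env$bundles)) return(.fixture_env$bundles)
  lib <- fixture_library()
  mm <- extract_mmrs(lib$mols, lib$annotations, lib$registry)
  ds <- build_reaction_datasets(mm)
  bundles <- list()
  for (rt in c("III", "IV")) {
    scr <- screen_negatives(ds[[rt]], seed = 7)
    ms <- build_modeling_set(ds[[rt]], scr$negatives, seed = 7)
    y <- factor(ifelse(ms$train$records$label == "positive", "pos", "neg"),
                c("neg", "pos"))
    search <- run_model_search(ms$train$vectors, y, fs_methods = "chi",
                               classifiers = c("BN", "IBK", "RF"),
                               folds = 5, seed = 7)
    sel <- select_optimal(search)
    bundles[[rt]] <- fit_final(ms$train$vectors, y, sel,
                               reaction_type = rt, seed = 7)
  }
  .fixture_env$bundles <- list(bundles = bundles, lib = lib, mm = mm)
  .fixture_env$bundles
}

test_that("per-bond calls are emitted only for matching patterns", {
  fb <- fixture_bundles()
  hexane <- parse_smiles_set("CCCCCC", "hexane")[[1]]
  calls <- predict_molecule(hexane, "CYP3A4", fb$bundles)
  expect_equal(nrow(calls[calls$reaction_type == "IV", ]), 0L)
  expect_equal(nrow(calls[calls$reaction_type == "III", ]), 0L)

  tma <- fixture_mol("trimethylamine")
  calls <- predict_molecule(tma, "CYP3A4", fb$bundles)
  expect_equal(unique(calls$reaction_type), "III")
  expect_equal(nrow(calls), 1L)          # three equivalent methyls collapse
  expect_true(all(calls$probability >= 0 & calls$probability <= 1))
  expect_true(all(calls$call %in% c("positive", "negative")))
  expect_error(predict_molecule(tma, "CYP9Z9", fb$bundles), "enzyme")
})

test_that("calls under different enzymes are independent and well-formed", {
  fb <- fixture_bundles()
  mol <- fb$lib$mols[[1]]
  c1 <- predict_molecule(mol, "CYP3A4", fb$bundles)
  c2 <- predict_molecule(mol, "CYP2C9", fb$bundles)
  expect_equal(nrow(c1), nrow(c2))       # same candidate bonds
  expect_equal(c1[c("atom_a", "atom_b", "reaction_type")],
               c2[c("atom_a", "atom_b", "reaction_type")])
  expect_equal(unique(c1$enzyme), "CYP3A4")
  expect_equal(unique(c2$enzyme), "CYP2C9")
})

test_that("prediction descriptors reproduce the training vectors exactly", {
  fb <- fixture_bundles()
  mm <- fb$mm
  idx <- which(mm$records$reaction_type == "IV")[1]
  rec <- mm$records[idx, ]
  mol <- fb$lib$mols[[match(rec$mol_id,
                            vapply(fb$lib$mols, function(m) m$mol_id, ""))]]
  v <- compute_descriptor_vector(protonate_ph74(mol), rec)
  expect_equal(unname(v), unname(mm$vectors[idx, ]), tolerance = 1e-12)
})

test_that("symmetry-equivalent bonds receive a single consistent call", {
  fb <- fixture_bundles()
  pdm <- fixture_mol("pdimethoxy")      # two equivalent aryl-OMe groups
  calls <- predict_molecule(pdm, "CYP3A4", fb$bundles)
  iv <- calls[calls$reaction_type == "IV", ]
  expect_equal(nrow(iv), 1L)            # collapsed to one class
})

test_that("planted sites of held-out molecules are recalled", {
  fb <- fixture_bundles()
  new_lib <- make_toy_library(30, seed = 99)
  mols <- parse_smiles_set(new_lib$smiles$smiles, new_lib$smiles$mol_id)
  res <- external_evaluate(mols, new_lib$annotations, fb$bundles,
                           registry = new_lib$registry)
  expect_equal(sum(res$by_reaction$n), res$n_total)
  expect_equal(sum(res$by_reaction$n_correct), res$n_correct)
  expect_equal(res$accuracy, res$n_correct / res$n_total)
  # per-MMRS recall of planted positives for the modeled reactions
  pos <- res$calls[res$calls$truth == "positive", ]
  expect_gte(mean(pos$call == "positive"), 0.9)
  expect_gt(res$accuracy, 0.9)
})
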