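test_that("SDF and SMILES structures parse with explicit hydrogens", {
  sdf <- file.path(tempdir(), "methane.sdf")
  writeLines(c("methane", "", "",
               "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "M  END", "$$$$"), sdf)
  mols <- read_structures(sdf, "sdf")
  expect_length(mols, 1L)
  expect_equal(nrow(mols[[1]]$atoms), 5L)       # 1 C + 4 explicit H
  expect_equal(sum(mols[[1]]$atoms$element == "H"), 4L)

  smi <- file.path(tempdir(), "lib.smi")
  writeLines(c("CCO\tethanol", "C\tmethane"), smi)
  mols <- read_structures(smi, "smiles")
  expect_length(mols, 2L)
  expect_equal(mols[[1]]$mol_id, "ethanol")
  expect_equal(nrow(mols[[1]]$atoms), 9L)       # C2H6O
})

test_that("empty and unparseable structure files raise errors", {
  f <- file.path(tempdir(), "empty.smi")
  writeLines(character(0), f)
  expect_error(read_structures(f, "smiles"), "empty")
  writeLines(c("not_a_smiles((("), f)
  expect_error(suppressWarnings(read_structures(f, "smiles")))
})

test_that("element filter removes disallowed elements and keeps halogens", {
  mols <- suppressWarnings(
    parse_smiles_set(c("C", "CB(C)C", "ClC(Cl)(Cl)Cl"),
                     c("methane", "boron_cpd", "carbontet")))
  res <- filter_elements(mols)
  expect_equal(vapply(res$kept, function(m) m$mol_id, ""),
               c("methane", "carbontet"))
  expect_equal(res$removed$mol_id, "boron_cpd")
  expect_equal(res$removed$element, "B")
  # idempotence
  res2 <- filter_elements(res$kept)
  expect_equal(vapply(res2$kept, function(m) m$mol_id, ""),
               c("methane", "carbontet"))
  expect_equal(nrow(res2$removed), 0L)
  # empty input
  expect_equal(filter_elements(list())$kept, list())
})

test_that("salts are stripped to the largest organic fragment", {
  mols <- parse_smiles_set("CCN.Cl", "amine_hcl")
  res <- filter_elements(mols)
  kept <- res$kept[[1]]
  expect_equal(sum(kept$atoms$element == "Cl"), 0L)
  expect_equal(sum(kept$atoms$element == "N"), 1L)
  expect_equal(kept$n_fragments, 1L)
})

test_that("SOM annotation reading validates and deduplicates", {
  f <- file.path(tempdir(), "som.tsv")
  writeLines(c("mol_id\tatom_a\tatom_b\tenzyme\treaction_type",
               "m1\t2\t7\tCYP3A4\tIII",
               "m1\t2\t7\tCYP3A4\tIII",
               "m2\t1\t0\t2d6\tI"), f)
  ann <- suppressMessages(read_som_annotations(f))
  expect_equal(nrow(ann), 2L)                  # duplicate collapsed
  expect_equal(ann$enzyme[2], "CYP2D6")        # normalized

  writeLines(c("mol_id\tatom_a\tatom_b\tenzyme\treaction_type",
               "m1\t2\t7\tCYP1A2\tIII"), f)
  expect_error(read_som_annotations(f), "CYP1A2")
  writeLines(c("mol_id\tatom_a\tatom_b\tenzyme\treaction_type",
               "m1\t2\t7\tCYP3A4\tV"), f)
  expect_error(read_som_annotations(f), "reaction_type")
})

test_that("MMRS table round-trips exactly through CSV", {
  lib <- fixture_library()
  mm <- extract_mmrs(lib$mols[1:8], lib$annotations, lib$registry)
  path <- file.path(tempdir(), "mmrs.csv")
  write_mmrs_table(mm$records, mm$vectors, path)
  back <- read_mmrs_table(path)
  expect_equal(back$records, mm$records)
  expect_equal(back$vectors, mm$vectors)
  # header carries the canonical labels
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_true(all(c("\"qtot_A\"", "\"boord\"", "\"CYP3A4\"") %in% header))
  # length mismatch
  expect_error(write_mmrs_table(mm$records[-1, ], mm$vectors, path),
               "differ")
})

test_that("model bundles persist and reproduce predictions", {
  ft <- make_feature_table(80, n_informative = 3, effect = 3, seed = 2)
  tab <- score_features(ft$X, ft$y, "chi", folds = 5, seed = 2)
  pruned <- prune_zero(tab)
  sel <- list(fs = "chi", classifier = "RF", size = 3L,
              feature_ids = pruned[1:6],
              feature_labels = attr(pruned, "labels")[1:6],
              acc = 1, auc = 1, se = 1, sp = 1, bacc = 1)
  sel$feature_labels <- colnames(ft$X)[sel$feature_ids]
  bundle <- fit_final(ft$X, ft$y, sel, reaction_type = "I", seed = 3)
  newX <- make_feature_table(10, n_informative = 3, effect = 3,
                             seed = 9)$X[, sel$feature_labels]
  p0 <- predict_classifier(bundle$model, newX)
  dir <- file.path(tempdir(), "bundle_test")
  save_model_bundle(bundle, dir)
  loaded <- load_model_bundle(dir)
  expect_equal(loaded$manifest$classifier, "RF")
  expect_length(loaded$manifest$feature_labels, 6L)
  expect_equal(predict_classifier(loaded$model, newX), p0)
  # corrupt estimator file
  writeLines("garbage", file.path(dir, "estimator.rds"))
  expect_error(load_model_bundle(dir), "corrupt")
})
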