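test_that("pattern enumeration matches the four bond definitions", {
  ben <- fixture_mol("benzene")
  expect_equal(nrow(enumerate_candidates(ben, "II")), 6L)
  expect_equal(nrow(enumerate_candidates(ben, "I")), 0L)

  eth <- fixture_mol("ethanol")
  # hydroxyl O has one heavy neighbor: no O-dealkylation candidate
  expect_equal(nrow(enumerate_candidates(eth, "IV")), 0L)
  expect_equal(nrow(enumerate_candidates(eth, "I")), 5L)

  ani <- fixture_mol("anisole")
  expect_equal(nrow(enumerate_candidates(ani, "IV")), 1L)
  expect_equal(nrow(enumerate_candidates(ani, "II")), 5L)

  tma <- fixture_mol("trimethylamine")
  expect_equal(nrow(enumerate_candidates(tma, "III")), 3L)

  # brute-force oracle: every C-H bond lands in exactly one of I/II
  for (nm in c("toluene", "anisole", "ethylbenzene")) {
    mol <- fixture_mol(nm)
    h_on_c <- sum(vapply(which(mol$atoms$element == "H"), function(h)
      mol$atoms$element[mol$adj[[h]]][1] == "C", TRUE))
    n1 <- nrow(enumerate_candidates(mol, "I"))
    n2 <- nrow(enumerate_candidates(mol, "II"))
    expect_equal(n1 + n2, h_on_c)
    both <- merge(enumerate_candidates(mol, "I"),
                  enumerate_candidates(mol, "II"))
    expect_equal(nrow(both), 0L)
  }
})

test_that("amide nitrogen exclusion switch narrows pattern III", {
  dma <- parse_smiles_set("CN(C)C(C)=O", "dimethylacetamide")[[1]]
  with_amide <- enumerate_candidates(dma, "III")
  without <- enumerate_candidates(dma, "III", exclude_amide_n = TRUE)
  expect_gt(nrow(with_amide), 0L)
  expect_equal(nrow(without), 0L)
})

test_that("symmetry collapsing merges equivalent bonds", {
  ben <- fixture_mol("benzene")
  cs <- collapse_symmetry(enumerate_candidates(ben, "II"), ben)
  expect_equal(nrow(cs$representatives), 1L)
  expect_equal(cs$representatives$class_size, 6L)

  eth <- fixture_mol("ethanol")
  cs <- collapse_symmetry(enumerate_candidates(eth, "I"), eth)
  expect_equal(nrow(cs$representatives), 2L)            # CH3 vs CH2
  expect_equal(sort(cs$representatives$class_size), c(2L, 3L))

  tol <- fixture_mol("toluene")
  expect_equal(nrow(collapse_symmetry(
    enumerate_candidates(tol, "I"), tol)$representatives), 1L)
  expect_equal(nrow(collapse_symmetry(
    enumerate_candidates(tol, "II"), tol)$representatives), 3L)

  # partition property: class sizes sum to the candidate count
  ani <- fixture_mol("anisole")
  cands <- enumerate_candidates(ani, "II")
  cs <- collapse_symmetry(cands, ani)
  expect_equal(sum(cs$representatives$class_size), nrow(cands))
  expect_equal(length(unique(cs$all$symmetry_class)),
               nrow(cs$representatives))
})

test_that("symmetry classes agree with brute-force automorphisms", {
  mols <- c(fixture_mols()[c("toluene", "anisole", "naphthalene",
                             "pdimethoxy", "tbutylbenzene", "dmae",
                             "trimethylamine")],
            fixture_library()$mols[1:10])
  checked <- 0L
  for (mol in mols) {
    if (length(heavy_atoms(mol)) > 12L) next
    for (rt in c("I", "II", "III", "IV")) {
      cands <- enumerate_candidates(mol, rt)
      if (nrow(cands) < 2L) next
      fast <- collapse_symmetry(cands, mol)$all$symmetry_class
      slow <- brute_pair_classes(mol, cands)
      expect_equal(partition_signature(fast), partition_signature(slow),
                   info = paste(mol$mol_id, rt))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("labeling marks annotated classes positive, everything else unlabeled", {
  ani <- fixture_mol("anisole")
  cs <- collapse_symmetry(enumerate_candidates(ani, "IV"), ani)
  ann <- data.frame(mol_id = "anisole", atom_a = 8L, atom_b = 7L,
                    enzyme = "CYP3A4", reaction_type = "IV")
  recs <- label_mmrs(ani, cs, "IV", ann, c("CYP3A4", "CYP2D6"))
  expect_equal(nrow(recs), 2L)                    # 1 class x 2 enzymes
  expect_equal(recs$label[recs$enzyme == "CYP3A4"], "positive")
  expect_equal(recs$label[recs$enzyme == "CYP2D6"], "unlabeled")

  # no annotations: all unlabeled
  recs <- label_mmrs(ani, cs, "IV",
                     ann[0, , drop = FALSE], "CYP3A4")
  expect_true(all(recs$label == "unlabeled"))

  # annotating one hydrogen of a methyl marks the whole class
  tol <- fixture_mol("toluene")
  cs1 <- collapse_symmetry(enumerate_candidates(tol, "I"), tol)
  h_of_methyl <- tol$adj[[1]][tol$atoms$element[tol$adj[[1]]] == "H"][2]
  ann <- data.frame(mol_id = "toluene", atom_a = 1L,
                    atom_b = tol$atoms$src[h_of_methyl],
                    enzyme = "CYP3A4", reaction_type = "I")
  recs <- label_mmrs(tol, cs1, "I", ann, "CYP3A4")
  expect_equal(recs$label, "positive")            # single methyl class

  # annotation that matches no enumerated candidate errors
  bad <- data.frame(mol_id = "toluene", atom_a = 3L, atom_b = 0L,
                    enzyme = "CYP3A4", reaction_type = "I")
  expect_error(label_mmrs(tol, cs1, "I", bad, "CYP3A4"),
               "no enumerated candidate")
})

test_that("reaction datasets partition the MMRS pool", {
  lib <- fixture_library()
  mm <- extract_mmrs(lib$mols, lib$annotations, lib$registry)
  ds <- build_reaction_datasets(mm)
  expect_named(ds, c("I", "II", "III", "IV"))
  expect_equal(sum(vapply(ds, function(d) nrow(d$records), 0L)),
               nrow(mm$records))
  for (d in ds) {
    expect_equal(unname(d$counts["positive"] + d$counts["unlabeled"] +
                        d$counts["negative"]), nrow(d$records))
    expect_true(all(d$records$label %in% c("positive", "unlabeled")))
  }
  # label conservation before screening
  expect_equal(sum(mm$records$label == "positive") +
               sum(mm$records$label == "unlabeled"), nrow(mm$records))
})

test_that("SOM distribution summary reproduces printed percentages", {
  counts <- c("Aliphatic C-hydroxylation" = 1411,
              "Aromatic C-hydroxylation" = 314,
              "N-dealkylation" = 347, "O-dealkylation" = 137,
              "S-oxidations" = 57, "N-oxidations" = 27,
              "Desulfurization" = 7, "Others" = 15)
  tab <- summarize_som_distribution(counts)
  pct <- stats::setNames(tab$percentage, tab$reaction_type)
  expect_equal(unname(pct["Aliphatic C-hydroxylation"]), 61)
  expect_equal(unname(pct["O-dealkylation"]), 5.9)
  expect_equal(unname(pct["Aromatic C-hydroxylation"]), 13.6)
  expect_equal(unname(pct["N-dealkylation"]), 15)
  # single reaction type normalizes to 100
  expect_equal(summarize_som_distribution(c(I = 42))$percentage, 100)
  expect_error(summarize_som_distribution(data.frame()), "summarize")
})
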