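test_that("pH 7.4 rules produce the expected microspecies", {
  gly <- protonate_ph74(fixture_mol("glycine"))
  expect_equal(sum(gly$atoms$charge), 0L)                # zwitterion
  expect_equal(gly$atoms$charge[gly$atoms$element == "N"], 1L)
  expect_equal(sort(gly$atoms$charge[gly$atoms$element == "O"]), c(-1L, 0L))

  ben <- protonate_ph74(fixture_mol("benzene"))
  expect_equal(ben$atoms, fixture_mol("benzene")$atoms)  # no ionizable group

  ace <- protonate_ph74(fixture_mol("acetic"))
  expect_equal(sum(ace$atoms$charge), -1L)               # acetate
  # one hydroxyl H removed
  expect_equal(sum(ace$atoms$element == "H"), 3L)

  tma <- protonate_ph74(fixture_mol("trimethylamine"))
  expect_equal(sum(tma$atoms$charge), 1L)                # aliphatic amine
  expect_equal(sum(tma$atoms$element == "H"), 10L)       # one H added

  # anilines and ethers stay neutral
  ani <- protonate_ph74(fixture_mol("anisole"))
  expect_equal(sum(ani$atoms$charge), 0L)
})

test_that("PEOE charges respect symmetry and conserve total charge", {
  meth <- fixture_mol("methane")
  pr <- compute_atomic_properties(meth)
  hq <- pr$q_tot[meth$atoms$element == "H"]
  expect_equal(max(hq) - min(hq), 0, tolerance = 1e-12)   # 4 equal H
  cq <- pr$q_tot[meth$atoms$element == "C"]
  expect_equal(cq, -4 * hq[1], tolerance = 1e-12)
  expect_lt(cq, 0)                                        # C more electronegative

  # conservation on every library fixture
  lib <- fixture_library()
  for (mol in lib$mols) {
    mol <- protonate_ph74(mol)
    pr <- compute_atomic_properties(mol)
    expect_lt(abs(sum(pr$q_tot) - sum(mol$atoms$charge)), 1e-6)
    expect_true(all(pr$pol > 0))
  }
})

test_that("PEOE charge pattern of ethanol is chemically sensible", {
  eth <- fixture_mol("ethanol")
  pr <- compute_atomic_properties(eth)
  qO <- pr$q_tot[eth$atoms$element == "O"]
  qC_methyl <- pr$q_tot[1]       # CH3, source order of "CCO"
  qC_carbinol <- pr$q_tot[2]     # CH2-O
  expect_lt(qO, qC_methyl)                 # O most negative
  expect_lt(qC_methyl, qC_carbinol)        # electron pull through the chain
  # pi charges are exactly zero in a saturated molecule
  expect_equal(pr$q_pi, rep(0, nrow(eth$atoms)))
  # ... and nonzero in an aromatic one
  prb <- compute_atomic_properties(fixture_mol("anisole"))
  expect_gt(max(abs(prb$q_pi)), 0)
})

test_that("descriptor vectors realize the neighborhood definitions", {
  meth <- fixture_mol("methane")
  dv <- compute_descriptor_vector(
    meth, list(atom_a = 1L, atom_b = 2L, enzyme = "CYP3A4",
               reaction_type = "I"))
  expect_length(dv, 59L)
  expect_equal(unname(dv[c("Hn_A", "Cn_A", "Csp3_A", "boord")]),
               c(3, 0, 1, 1))
  expect_equal(unname(dv[c("CYP3A4", "CYP2D6", "CYP2C9")]), c(1, 0, 0))
  # B = H has no further neighbor: sentinel zeros
  expect_equal(unname(dv[c("maxqtot_B", "minpol_B", "Hn_B", "Cn_B")]),
               c(0, 0, 0, 0))

  ben <- fixture_mol("benzene")
  h <- which(ben$atoms$element == "H")[1]
  dvb <- compute_descriptor_vector(
    ben, list(atom_a = ben$adj[[h]][1], atom_b = h,
              enzyme = "CYP2D6", reaction_type = "II"))
  expect_equal(unname(dvb[c("Csp2_neigA", "Hn_A", "boord", "Csp2_A")]),
               c(2, 0, 1, 1))

  # trimethylamine C-N bond: A = methyl carbon, B = N
  tma <- fixture_mol("trimethylamine")
  pr <- compute_atomic_properties(tma)
  dvt <- compute_descriptor_vector(
    tma, list(atom_a = 1L, atom_b = 2L, enzyme = "CYP3A4",
              reaction_type = "III"), props = pr)
  expect_equal(unname(dvt["Hn_A"]), 3)
  expect_equal(unname(dvt["Cn_B"]), 2)          # two other methyls
  expect_equal(unname(dvt["dqtot"]), pr$q_tot[1] - pr$q_tot[2])

  # orientation mismatch errors
  expect_error(compute_descriptor_vector(
    tma, list(atom_a = 1L, atom_b = 2L, enzyme = "CYP3A4",
              reaction_type = "IV")), "expects")
})

test_that("descriptors are deterministic and invariant to atom renumbering", {
  ani <- fixture_mol("anisole")
  mm1 <- compute_descriptor_vector(
    ani, list(atom_a = 8L, atom_b = 7L, enzyme = "CYP3A4",
              reaction_type = "IV"))
  mm2 <- compute_descriptor_vector(
    ani, list(atom_a = 8L, atom_b = 7L, enzyme = "CYP3A4",
              reaction_type = "IV"))
  expect_identical(mm1, mm2)
  # same molecule written with a different atom order
  ani2 <- parse_smiles_set("COc1ccccc1", "anisole2")[[1]]
  mm3 <- compute_descriptor_vector(
    ani2, list(atom_a = 1L, atom_b = 2L, enzyme = "CYP3A4",
               reaction_type = "IV"))
  expect_equal(unname(mm3), unname(mm1), tolerance = 1e-12)
})

test_that("A-side descriptors ignore substituents added beyond B", {
  # anisole vs p-dimethoxybenzene: the methyl-O MMRS A-neighborhood
  # (B excluded) must not change when the ring gains a remote substituent
  a_cols <- c("maxqtot_A", "minqtot_A", "maxpol_A", "minpol_A",
              "Hn_A", "Cn_A", "Nn_A", "On_A", "Pn_A", "Sn_A", "Xn_A")
  ani <- fixture_mol("anisole")
  v1 <- compute_descriptor_vector(
    ani, list(atom_a = 8L, atom_b = 7L, enzyme = "CYP3A4",
              reaction_type = "IV"))
  pdm <- fixture_mol("pdimethoxy")    # "c1cc(OC)ccc1OC": O7 C8 like anisole?
  # locate a methyl-O bond in the p-dimethoxy molecule
  cand <- enumerate_candidates(pdm, "IV")[1, ]
  v2 <- compute_descriptor_vector(
    pdm, list(atom_a = pdm$atoms$src[cand$a], atom_b = pdm$atoms$src[cand$b],
              enzyme = "CYP3A4", reaction_type = "IV"))
  # topological A-side counts identical (charges differ slightly by design)
  top_cols <- c("Hn_A", "Cn_A", "Nn_A", "On_A", "Pn_A", "Sn_A", "Xn_A")
  expect_equal(v1[top_cols], v2[top_cols])
})

test_that("enzyme encoding is a strict one-hot with normalization", {
  expect_equal(unname(encode_enzyme("CYP3A4")), c(1, 0, 0))
  expect_equal(unname(encode_enzyme("CYP2D6")), c(0, 1, 0))
  expect_equal(unname(encode_enzyme("3a4")), c(1, 0, 0))
  expect_error(encode_enzyme("CYP1A2"), "unknown")
  man <- descriptor_manifest()
  expect_equal(nrow(man), 59L)
  expect_equal(man$label[56], "boord")
  expect_equal(man$label[1], "qtot_A")
})
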