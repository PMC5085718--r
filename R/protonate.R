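#' Rule-based major microspecies at pH 7.4
#'
#' Physiological pH determines which ionizable groups of a substrate are
#' charged; descriptors are therefore computed on the major microspecies at
#' pH 7.4 obtained from a small, fixed rule table rather than a pKa engine:
#'
#' * deprotonated (-1 on O): carboxylic acids, sulfonic acids, acidic P-OH
#'   groups (phosphonic/phosphate), tetrazole N-H;
#' * protonated (+1 on N, one H added): aliphatic amines (sp3 N, neutral,
#'   all heavy neighbors sp3 carbons), and the imino N of
#'   amidines/guanidines;
#' * left neutral: anilines, amides, sulfonamides, alcohols, phenols,
#'   pyridines.
#'
#' The rules cover pKa values clearly on one side of 7.4; borderline groups
#' (e.g. imidazoles, phenols) stay neutral by design.
#'
#' @param mol an [mmrs_mol] with explicit hydrogens.
#' @return the adjusted molecule (hydrogen count and formal charges updated;
#'   hydrogens added by this step get fresh source indices past the input's
#'   numbering).
#' @export
protonate_ph74 <- function(mol) {
  el <- mol$atoms$element
  # --- acidic O-H -> O(-) ---------------------------------------------------
  drop_h <- integer(0)
  for (o in which(el == "O")) {
    nb <- mol$adj[[o]]
    hs <- nb[el[nb] == "H"]
    if (!length(hs)) next
    heavy <- nb[el[nb] != "H"]
    if (length(heavy) != 1L) next
    x <- heavy[1]
    if (is_acidic_center(mol, x, o)) {
      drop_h <- c(drop_h, hs[1])
      mol$atoms$charge[o] <- mol$atoms$charge[o] - 1L
    }
  }
  # --- tetrazole N-H -> N(-) ------------------------------------------------
  for (ring in find_rings(mol, max_len = 5L)) {
    if (length(ring) != 5L) next
    if (sum(el[ring] == "N") < 4L) next
    if (!all(mol$atoms$aromatic[ring])) next
    for (nn in ring[el[ring] == "N"]) {
      hs <- mol$adj[[nn]][el[mol$adj[[nn]]] == "H"]
      if (length(hs)) {
        drop_h <- c(drop_h, hs[1])
        mol$atoms$charge[nn] <- mol$atoms$charge[nn] - 1L
        break
      }
    }
  }
  if (length(drop_h))
    mol <- subset_mol_keep_charge(mol, setdiff(seq_len(n_atoms(mol)), drop_h))
  # --- basic N -> N(+) ------------------------------------------------------
  el <- mol$atoms$element
  add_h_to <- integer(0)
  for (nn in which(el == "N")) {
    if (mol$atoms$charge[nn] != 0L) next
    if (mol$atoms$aromatic[nn]) next
    nb <- mol$adj[[nn]]
    heavy <- nb[el[nb] != "H"]
    ks <- mol$bond_idx[[nn]]
    if (any(mol$bonds$order[ks] >= 2L)) {
      # imino N of an amidine/guanidine: C(=N) with another N on that C
      cpart <- mol$adj[[nn]][mol$bonds$order[ks] == 2L]
      if (length(cpart) == 1L && el[cpart] == "C" &&
          !mol$atoms$aromatic[cpart] &&
          sum(el[mol$adj[[cpart]]] == "N") >= 2L)
        add_h_to <- c(add_h_to, nn)
      next
    }
    if (length(heavy) && all(el[heavy] == "C") &&
        all(mol$atoms$hyb[heavy] == "sp3") &&
        !any(vapply(heavy, function(c_at) is_acyl_carbon(mol, c_at), TRUE)))
      add_h_to <- c(add_h_to, nn)
  }
  if (length(add_h_to)) {
    for (nn in add_h_to) {
      mol$atoms <- rbind(mol$atoms[c("element", "charge", "src")],
                         data.frame(element = "H", charge = 0L,
                                    src = max(mol$atoms$src) + 1L))
      mol$atoms$charge[nn] <- mol$atoms$charge[nn] + 1L
      mol$bonds <- rbind(mol$bonds[c("a", "b", "order", "aromatic")],
                         data.frame(a = nn, b = nrow(mol$atoms),
                                    order = 1L, aromatic = FALSE))
      mol <- rebuild_mol(mol)
    }
  } else {
    mol <- rebuild_mol(mol)
  }
  mol
}

# is x (bonded to the probed hydroxyl O `o_probe`) an acidic center?
is_acidic_center <- function(mol, x, o_probe) {
  el <- mol$atoms$element
  ks <- mol$bond_idx[[x]]
  dbl_o <- sum(el[mol$adj[[x]]] == "O" & mol$bonds$order[ks] == 2L)
  switch(el[x],
         "C" = dbl_o >= 1L,            # carboxylic acid
         "S" = dbl_o >= 2L,            # sulfonic acid
         "P" = dbl_o >= 1L,            # phosphonic / phosphate
         FALSE)
}

is_acyl_carbon <- function(mol, c_at) {
  el <- mol$atoms$element
  ks <- mol$bond_idx[[c_at]]
  any(el[mol$adj[[c_at]]] %in% c("O", "S") & mol$bonds$order[ks] == 2L)
}

# subset that preserves already-updated charges (subset_mol semantics)
subset_mol_keep_charge <- function(mol, keep) subset_mol(mol, keep)
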