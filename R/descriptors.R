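#' @title The 56 bond descriptors
#'
#' @description Each MMRS bond (A, B) is characterized by 29 physicochemical
#' and 27 topological descriptors.  A is always the reacting carbon, B the
#' partner atom (H for C-hydroxylations, N for N-dealkylation, O for
#' O-dealkylation).  Neighbor statistics of A exclude B and vice versa
#' (descriptors 17-24 and 30-43); a max/min over an empty neighbor set is
#' reported as the 0 sentinel.  The carbon-hybridization neighbor counts
#' (50-55) count all carbon neighbors including the partner, matching their
#' definition.  Aromatic bonds carry bond order 1.5.
#' @name descriptors
NULL

DESCRIPTOR_LABELS <- c(
  "qtot_A", "qsigma_A", "qpi_A", "pol_A", "oensigma_A", "oenpi_A",
  "pichgdens_A", "totchgdens_A",
  "qtot_B", "qsigma_B", "qpi_B", "pol_B", "oensigma_B", "oenpi_B",
  "pichgdens_B", "totchgdens_B",
  "maxqtot_A", "minqtot_A", "maxqtot_B", "minqtot_B",
  "maxpol_A", "minpol_A", "maxpol_B", "minpol_B",
  "dqtot", "dqsigma", "dqpi", "doensigma", "doenpi",
  "Hn_A", "Cn_A", "Nn_A", "On_A", "Pn_A", "Sn_A", "Xn_A",
  "Hn_B", "Cn_B", "Nn_B", "On_B", "Pn_B", "Sn_B", "Xn_B",
  "Csp1_A", "Csp2_A", "Csp3_A", "Csp1_B", "Csp2_B", "Csp3_B",
  "Csp1_neigA", "Csp2_neigA", "Csp3_neigA",
  "Csp1_neigB", "Csp2_neigB", "Csp3_neigB",
  "boord")

DESCRIPTOR_DESCRIPTIONS <- c(
  "total charge of A", "sigma charge of A", "pi charge of A",
  "polarizability of A", "sigma orbital-electronegativity of A",
  "pi orbital-electronegativity of A", "pi charge density of A",
  "total charge density of A",
  "total charge of B", "sigma charge of B", "pi charge of B",
  "polarizability of B", "sigma orbital-electronegativity of B",
  "pi orbital-electronegativity of B", "pi charge density of B",
  "total charge density of B",
  "maximum charge of A neighbors (except B)",
  "minimum charge of A neighbors (except B)",
  "maximum charge of B neighbors (except A)",
  "minimum charge of B neighbors (except A)",
  "maximum polarizability of A neighbors (except B)",
  "minimum polarizability of A neighbors (except B)",
  "maximum polarizability of B neighbors (except A)",
  "minimum polarizability of B neighbors (except A)",
  "difference of total charges", "difference of sigma charges",
  "difference of pi charges",
  "difference of sigma orbital-electronegativity",
  "difference of pi orbital-electronegativity",
  "number of H-atoms bonded to A (except B)",
  "number of C-atoms bonded to A (except B)",
  "number of N-atoms bonded to A (except B)",
  "number of O-atoms bonded to A (except B)",
  "number of P-atoms bonded to A (except B)",
  "number of S-atoms bonded to A (except B)",
  "number of halogen atoms bonded to A (except B)",
  "number of H-atoms bonded to B (except A)",
  "number of C-atoms bonded to B (except A)",
  "number of N-atoms bonded to B (except A)",
  "number of O-atoms bonded to B (except A)",
  "number of P-atoms bonded to B (except A)",
  "number of S-atoms bonded to B (except A)",
  "number of halogen atoms bonded to B (except A)",
  "A is C sp1", "A is C sp2", "A is C sp3",
  "B is C sp1", "B is C sp2", "B is C sp3",
  "number of C sp1 neighbors of A", "number of C sp2 neighbors of A",
  "number of C sp3 neighbors of A",
  "number of C sp1 neighbors of B", "number of C sp2 neighbors of B",
  "number of C sp3 neighbors of B",
  "bond order")

#' Canonical feature names of an MMRS descriptor vector
#'
#' The 56 bond-descriptor labels followed by the three enzyme indicator
#' columns.
#'
#' @return character vector of length 59.
#' @export
mmrs_feature_names <- function() c(DESCRIPTOR_LABELS, ENZYMES)

#' Descriptor manifest for audit
#'
#' @return data.frame with columns `id`, `label`, `description` for the 56
#'   bond descriptors and the 3 enzyme indicators.
#' @export
descriptor_manifest <- function() {
  data.frame(id = seq_len(59L),
             label = mmrs_feature_names(),
             description = c(DESCRIPTOR_DESCRIPTIONS,
                             paste("enzyme indicator:", ENZYMES)),
             stringsAsFactors = FALSE)
}

#' One-hot enzyme encoding
#'
#' @param enzyme enzyme name; case and a missing "CYP" prefix are tolerated
#'   (`"3a4"` normalizes to `"CYP3A4"`).
#' @return named numeric vector of three 0/1 indicators.
#' @export
encode_enzyme <- function(enzyme) {
  e <- normalize_enzyme(enzyme)
  if (!(e %in% ENZYMES)) stop("unknown enzyme: ", enzyme)
  stats::setNames(as.numeric(ENZYMES == e), ENZYMES)
}

# the 56-element descriptor vector for the oriented bond (A, B)
descriptor_values <- function(mol, props, A, B) {
  el <- mol$atoms$element
  hyb <- mol$atoms$hyb
  nA <- setdiff(mol$adj[[A]], B)
  nB <- setdiff(mol$adj[[B]], A)
  mm <- function(x, f) if (length(x)) f(x) else 0
  cnt <- function(nb, set) sum(el[nb] %in% set)
  k <- bond_between(mol, A, B)
  boord <- if (mol$bonds$aromatic[k]) 1.5 else mol$bonds$order[k]
  is_c <- function(i, h) as.numeric(el[i] == "C" && hyb[i] == h)
  csp_n <- function(i, h) sum(el[mol$adj[[i]]] == "C" & hyb[mol$adj[[i]]] == h)
  v <- c(
    props$q_tot[A], props$q_sigma[A], props$q_pi[A], props$pol[A],
    props$oen_sigma[A], props$oen_pi[A], props$pichgdens[A],
    props$totchgdens[A],
    props$q_tot[B], props$q_sigma[B], props$q_pi[B], props$pol[B],
    props$oen_sigma[B], props$oen_pi[B], props$pichgdens[B],
    props$totchgdens[B],
    mm(props$q_tot[nA], max), mm(props$q_tot[nA], min),
    mm(props$q_tot[nB], max), mm(props$q_tot[nB], min),
    mm(props$pol[nA], max), mm(props$pol[nA], min),
    mm(props$pol[nB], max), mm(props$pol[nB], min),
    props$q_tot[A] - props$q_tot[B],
    props$q_sigma[A] - props$q_sigma[B],
    props$q_pi[A] - props$q_pi[B],
    props$oen_sigma[A] - props$oen_sigma[B],
    props$oen_pi[A] - props$oen_pi[B],
    cnt(nA, "H"), cnt(nA, "C"), cnt(nA, "N"), cnt(nA, "O"),
    cnt(nA, "P"), cnt(nA, "S"), cnt(nA, HALOGENS),
    cnt(nB, "H"), cnt(nB, "C"), cnt(nB, "N"), cnt(nB, "O"),
    cnt(nB, "P"), cnt(nB, "S"), cnt(nB, HALOGENS),
    is_c(A, "sp"), is_c(A, "sp2"), is_c(A, "sp3"),
    is_c(B, "sp"), is_c(B, "sp2"), is_c(B, "sp3"),
    csp_n(A, "sp"), csp_n(A, "sp2"), csp_n(A, "sp3"),
    csp_n(B, "sp"), csp_n(B, "sp2"), csp_n(B, "sp3"),
    boord)
  stats::setNames(v, DESCRIPTOR_LABELS)
}

#' Compute the descriptor vector of one MMRS
#'
#' @param mol the (protonated) molecule.
#' @param mmrs a one-row MMRS record (needs `atom_a`, `atom_b`, `enzyme`,
#'   `reaction_type`; atom indices in source numbering).
#' @param props optional precomputed [compute_atomic_properties] result.
#' @return named numeric vector of length 59 (56 descriptors + enzyme
#'   one-hot).
#' @export
compute_descriptor_vector <- function(mol, mmrs, props = NULL) {
  if (is.null(props)) props <- compute_atomic_properties(mol)
  A <- src_to_internal(mol, mmrs$atom_a)
  B <- src_to_internal(mol, mmrs$atom_b)
  if (is.na(A) || is.na(B))
    stop("MMRS atoms not present in molecule '", mol$mol_id, "'")
  elA <- mol$atoms$element[A]; elB <- mol$atoms$element[B]
  want_b <- c(I = "H", II = "H", III = "N", IV = "O")[[mmrs$reaction_type]]
  if (elA != "C" || elB != want_b)
    stop("reaction type ", mmrs$reaction_type, " expects a C-", want_b,
         " bond, got ", elA, "-", elB)
  c(descriptor_values(mol, props, A, B), encode_enzyme(mmrs$enzyme))
}
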