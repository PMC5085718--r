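#' @title PEOE partial charges and atomic properties
#'
#' @description Sigma charges follow the classical damped partial
#' equalization of orbital electronegativities (PEOE): each atom carries a
#' quadratic electronegativity function chi(q) = a + b q + c q^2 of its
#' charge; in every iteration charge flows across each bond from the less
#' to the more electronegative atom, scaled by the donor's cation
#' electronegativity and damped by (1/2)^k, which converges in a handful of
#' iterations and conserves total charge exactly.  Parameters are the
#' published sigma values per element and hybridization (phosphorus uses
#' the values of the common open-source extension of the original table).
#'
#' Pi charges are obtained by the same damped equalization restricted to
#' the conjugated subsystem (atoms in double/triple/aromatic bonds plus
#' lone-pair donor N/O/S attached to such atoms) with an approximate pi
#' parameter table; atoms outside any conjugated system have pi charge
#' exactly 0.  The pi table is a declared approximation chosen to give the
#' qualitative mesomeric directions (lone-pair donors acquire positive,
#' acceptor neighborhoods negative pi charge); no claim of equivalence to
#' any proprietary charge model is made.
#' @name peoe
NULL

# sigma PEOE parameters: a, b, c per element(.hybridization)
PEOE_SIGMA <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S      = c(10.14, 9.13, 1.38),
  P      = c(8.90, 8.24, 0.96))

# approximate pi parameters (see block comment above)
PEOE_PI <- list(
  C = c(5.60, 8.93, 0.73),
  N = c(7.95, 9.73, 0.27),   # pi-bonded N
  O = c(10.09, 13.25, 0.44), # pi-bonded O (e.g. carbonyl)
  S = c(7.39, 8.20, 0.22),
  N.lp = c(4.00, 9.73, 0.27),# lone-pair donor N (aniline/amide type)
  O.lp = c(5.00, 13.25, 0.44),
  S.lp = c(4.50, 8.20, 0.22))

# Miller-style atomic hybrid polarizability contributions (A^3)
POLARIZABILITY <- list(
  H = 0.387,
  C.sp3 = 1.061, C.sp2 = 1.352, C.sp = 1.283,
  N.sp3 = 0.964, N.sp2 = 1.030, N.sp = 0.956,
  O.sp3 = 0.637, O.sp2 = 0.569,
  F = 0.296, Cl = 2.315, Br = 3.013, I = 5.415,
  S = 2.990, P = 1.538)

# Bondi van der Waals radii (Angstrom)
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

sigma_param_key <- function(element, hyb) {
  if (element %in% c("C", "N", "O")) paste(element, hyb, sep = ".")
  else element
}

lookup_params <- function(tbl, keys, what) {
  m <- tbl[keys]
  miss <- vapply(m, is.null, TRUE)
  if (any(miss))
    stop("no ", what, " parameters for atom type(s): ",
         paste(unique(keys[miss]), collapse = ", "))
  do.call(rbind, m)
}

#' Sigma PEOE partial charges
#'
#' @param mol an [mmrs_mol] with explicit hydrogens.
#' @param n_iter iterations of the damped equalization (default 8).
#' @return list with `q` (charges, e), `chi` (sigma orbital
#'   electronegativity at the converged charge, eV).
#' @export
peoe_sigma_charges <- function(mol, n_iter = 8L) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  keys <- vapply(seq_len(n), function(i) {
    hyb <- mol$atoms$hyb[i]
    # O in sp3 state unless doubly bonded; sp params only exist for C/N
    if (el[i] == "O" && hyb == "sp") hyb <- "sp2"
    sigma_param_key(el[i], hyb)
  }, "")
  par <- lookup_params(PEOE_SIGMA, keys, "sigma PEOE")
  a <- par[, 1]; b <- par[, 2]; cc <- par[, 3]
  chi_plus <- a + b + cc
  chi_plus[el == "H"] <- 20.02
  q <- as.numeric(mol$atoms$charge)
  ba <- mol$bonds$a; bb <- mol$bonds$b
  for (k in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    damp <- 0.5^k
    dchi <- chi[bb] - chi[ba]
    donor_plus <- ifelse(dchi > 0, chi_plus[ba], chi_plus[bb])
    dq <- damp * dchi / donor_plus   # charge gained by `a`, lost by `b`
    for (e in seq_along(ba)) {
      q[ba[e]] <- q[ba[e]] + dq[e]
      q[bb[e]] <- q[bb[e]] - dq[e]
    }
  }
  list(q = q, chi = a + b * q + cc * q^2)
}

# conjugation: pi-bonded atoms plus lone-pair donors attached to them
pi_system <- function(mol) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  has_pi_bond <- logical(n)
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] >= 2L || mol$bonds$aromatic[k]) {
      has_pi_bond[mol$bonds$a[k]] <- TRUE
      has_pi_bond[mol$bonds$b[k]] <- TRUE
    }
  }
  donor <- logical(n)
  for (i in which(!has_pi_bond & el %in% c("N", "O", "S"))) {
    if (any(has_pi_bond[mol$adj[[i]]])) donor[i] <- TRUE
  }
  list(member = has_pi_bond | donor, donor = donor)
}

#' Pi PEOE partial charges
#'
#' @inheritParams peoe_sigma_charges
#' @return list with `q` (pi charges; exactly 0 outside conjugated
#'   systems), `chi` (pi orbital electronegativity; 0 for atoms without pi
#'   parameters or outside the pi system).
#' @export
peoe_pi_charges <- function(mol, n_iter = 8L) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  ps <- pi_system(mol)
  q <- numeric(n); chi_out <- numeric(n)
  idx <- which(ps$member & el %in% c("C", "N", "O", "S"))
  if (length(idx) < 2L) return(list(q = q, chi = chi_out))
  keys <- ifelse(ps$donor[idx], paste0(el[idx], ".lp"), el[idx])
  par <- lookup_params(PEOE_PI, keys, "pi PEOE")
  a <- numeric(n); b <- numeric(n); cc <- numeric(n)
  a[idx] <- par[, 1]; b[idx] <- par[, 2]; cc[idx] <- par[, 3]
  chi_plus <- a + b + cc
  # pi-transfer edges: multiple/aromatic bonds, plus donor-to-pi single bonds
  keep <- logical(nrow(mol$bonds))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a[k]; j <- mol$bonds$b[k]
    if (!(i %in% idx) || !(j %in% idx)) next
    if (mol$bonds$order[k] >= 2L || mol$bonds$aromatic[k]) keep[k] <- TRUE
    else if (ps$donor[i] || ps$donor[j]) keep[k] <- TRUE
  }
  ba <- mol$bonds$a[keep]; bb <- mol$bonds$b[keep]
  if (!length(ba)) return(list(q = q, chi = chi_out))
  for (k in seq_len(n_iter)) {
    chi <- a + b * q + cc * q^2
    damp <- 0.5^k
    dchi <- chi[bb] - chi[ba]
    donor_plus <- ifelse(dchi > 0, chi_plus[ba], chi_plus[bb])
    dq <- damp * dchi / donor_plus
    for (e in seq_along(ba)) {
      q[ba[e]] <- q[ba[e]] + dq[e]
      q[bb[e]] <- q[bb[e]] - dq[e]
    }
  }
  chi_out[idx] <- (a + b * q + cc * q^2)[idx]
  list(q = q, chi = chi_out)
}

#' Per-atom physicochemical properties of a molecule
#'
#' Computes, for every atom: sigma/pi/total PEOE charge, sigma and pi
#' orbital electronegativity at the converged charge, an atomic-hybrid
#' polarizability contribution, and charge densities defined as charge per
#' van der Waals sphere surface (q / 4 pi r^2).
#'
#' @param mol an [mmrs_mol] (protonated, explicit hydrogens).
#' @return list of numeric vectors: `q_sigma`, `q_pi`, `q_tot`,
#'   `oen_sigma`, `oen_pi`, `pol`, `pichgdens`, `totchgdens`.
#' @export
compute_atomic_properties <- function(mol) {
  sig <- peoe_sigma_charges(mol)
  pii <- peoe_pi_charges(mol)
  el <- mol$atoms$element
  pol_keys <- vapply(seq_len(n_atoms(mol)), function(i) {
    hyb <- mol$atoms$hyb[i]
    if (el[i] == "O" && hyb == "sp") hyb <- "sp2"
    if (el[i] %in% c("C", "N", "O")) paste(el[i], hyb, sep = ".") else el[i]
  }, "")
  pol <- as.numeric(lookup_params(POLARIZABILITY, pol_keys,
                                  "polarizability"))
  r <- VDW_RADII[el]
  surf <- 4 * pi * r^2
  q_tot <- sig$q + pii$q
  list(q_sigma = sig$q, q_pi = pii$q, q_tot = q_tot,
       oen_sigma = sig$chi, oen_pi = pii$chi, pol = pol,
       pichgdens = pii$q / surf, totchgdens = q_tot / surf)
}
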