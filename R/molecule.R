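#' @title Molecular graph container
#'
#' @description Internal light-weight molecular graph used throughout the
#' package.  Atoms carry element symbol, formal charge and the 1-based index
#' they had in the source file (`src`), so site calls can always be reported
#' against the input's own numbering.  Bonds carry an integer order (1, 2, 3)
#' plus an aromatic flag perceived from the kekulized input.
#'
#' @name mmrs_mol
NULL

PERMITTED_ELEMENTS <- c("C", "H", "O", "N", "S", "P", "F", "Cl", "Br", "I")
HALOGENS <- c("F", "Cl", "Br", "I")

#' Construct a molecule record
#'
#' @param mol_id character scalar identifier.
#' @param elements character vector of element symbols, one per atom.
#' @param charges integer vector of formal charges (same length).
#' @param bonds data.frame with columns `a`, `b` (1-based atom indices) and
#'   `order` (1, 2, 3, or 4 for an aromatic bond as written by some SDF
#'   sources).
#' @param src optional integer vector mapping each atom to its 1-based index
#'   in the source file; defaults to `seq_along(elements)`.
#' @return An object of class `mmrs_mol`: a list with `mol_id`, `atoms`
#'   (data.frame: element, charge, src, aromatic, hyb), `bonds` (data.frame:
#'   a, b, order, aromatic), `adj` (adjacency list), and `n_fragments`.
#' @export
mmrs_mol <- function(mol_id, elements, charges = NULL, bonds, src = NULL) {
  n <- length(elements)
  if (is.null(charges)) charges <- integer(n)
  if (is.null(src)) src <- seq_len(n)
  stopifnot(length(charges) == n, length(src) == n)
  bonds <- as.data.frame(bonds)
  names(bonds)[1:3] <- c("a", "b", "order")
  if (nrow(bonds)) {
    if (any(bonds$a < 1 | bonds$a > n | bonds$b < 1 | bonds$b > n))
      stop("bond endpoint outside atom range in molecule '", mol_id, "'")
    if (any(bonds$a == bonds$b))
      stop("self-bond in molecule '", mol_id, "'")
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key))
      stop("duplicate bond in molecule '", mol_id, "'")
  }
  # SDF order code 4 means aromatic; normalize to order 1 + explicit flag,
  # final aromatic perception happens below over kekulized rings too.
  arom_bond <- bonds$order == 4
  bonds$order[arom_bond] <- 1L
  bonds$aromatic <- arom_bond
  mol <- structure(list(
    mol_id = as.character(mol_id),
    atoms = data.frame(element = as.character(elements),
                       charge = as.integer(charges),
                       src = as.integer(src),
                       stringsAsFactors = FALSE),
    bonds = bonds
  ), class = "mmrs_mol")
  rebuild_mol(mol)
}

# Recompute adjacency, aromaticity, hybridization and fragment count after
# any structural edit.  Always returns the molecule.
rebuild_mol <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  bi <- vector("list", n)   # indices into bonds, parallel to adj
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      bi[[a]] <- c(bi[[a]], k);  bi[[b]] <- c(bi[[b]], k)
    }
  }
  mol$adj <- adj
  mol$bond_idx <- bi
  mol <- perceive_aromaticity(mol)
  mol <- assign_hybridization(mol)
  mol$n_fragments <- as.integer(count_fragments(mol))
  mol
}

n_atoms <- function(mol) nrow(mol$atoms)

heavy_atoms <- function(mol) which(mol$atoms$element != "H")

neighbors_of <- function(mol, i) mol$adj[[i]]

bond_between <- function(mol, i, j) {
  k <- mol$bond_idx[[i]]
  k[mol$bonds$a[k] == j | mol$bonds$b[k] == j][1]
}

count_fragments <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(0L)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s; comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (w in mol$adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  attr(cur, "membership") <- comp
  cur
}

# ---- ring perception -------------------------------------------------------

# Smallest ring through each bond (length <= max_len), found by BFS on the
# graph with that bond removed.  Returns a list of unique atom-index cycles.
find_rings <- function(mol, max_len = 7L) {
  rings <- list()
  seen <- character(0)
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(rings)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    if (mol$atoms$element[a] == "H" || mol$atoms$element[b] == "H") next
    path <- bfs_path(mol, a, b, skip_bond = k, max_len = max_len - 1L)
    if (is.null(path)) next
    ring <- path  # a ... b, closing bond k
    key <- paste(sort(ring), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- ring }
  }
  rings
}

bfs_path <- function(mol, from, to, skip_bond, max_len) {
  n <- n_atoms(mol)
  prev <- integer(n); dist <- rep(NA_integer_, n)
  dist[from] <- 0L; queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (dist[v] >= max_len) next
    ks <- mol$bond_idx[[v]]
    for (idx in seq_along(ks)) {
      k <- ks[idx]
      if (k == skip_bond) next
      w <- mol$adj[[v]][idx]
      if (mol$atoms$element[w] == "H") next
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; prev[w] <- v
        if (w == to) {
          path <- w
          while (path[1] != from) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# Hueckel-style perception over small rings of kekulized input.  An atom
# contributes 1 pi electron if it has a double bond inside the ring, 2 if it
# is an N/O/S donating a lone pair (no in-ring double bond), and blocks
# aromaticity if it is a saturated carbon.  A ring with 4n+2 electrons and no
# blocking atom is marked aromatic.  Bonds already flagged aromatic (SDF
# order 4) are honored as-is.
perceive_aromaticity <- function(mol) {
  n <- n_atoms(mol)
  atom_ar <- logical(n)
  if (nrow(mol$bonds)) {
    atom_ar[mol$bonds$a[mol$bonds$aromatic]] <- TRUE
    atom_ar[mol$bonds$b[mol$bonds$aromatic]] <- TRUE
  }
  rings <- find_rings(mol)
  for (ring in rings) {
    m <- length(ring)
    if (m < 5L || m > 7L) next
    pe <- 0L; ok <- TRUE
    for (pos in seq_len(m)) {
      i <- ring[pos]
      el <- mol$atoms$element[i]
      nxt <- ring[if (pos == m) 1L else pos + 1L]
      prv <- ring[if (pos == 1L) m else pos - 1L]
      ks <- mol$bond_idx[[i]]
      ords <- mol$bonds$order[ks]
      aroms <- mol$bonds$aromatic[ks]
      nbrs <- mol$adj[[i]]
      in_ring_dbl <- any(nbrs %in% c(nxt, prv) & (ords == 2L | aroms))
      any_dbl <- any(ords >= 2L)
      if (in_ring_dbl) {
        pe <- pe + 1L
      } else if (el %in% c("N", "O", "S") && !any_dbl) {
        pe <- pe + 2L
      } else if (el == "C" && !any_dbl) {
        ok <- FALSE; break   # saturated ring carbon
      } else {
        # exocyclic double bond (e.g. ring C=O): contributes no electron but
        # does not block (covers e.g. pyridinone-type rings crudely)
        pe <- pe + 0L
      }
    }
    if (ok && pe %% 4L == 2L) atom_ar[ring] <- TRUE
  }
  # a bond is aromatic iff both ends are aromatic atoms and it lies in a ring
  if (nrow(mol$bonds)) {
    for (ring in rings) {
      if (all(atom_ar[ring])) {
        m <- length(ring)
        for (pos in seq_len(m)) {
          i <- ring[pos]; j <- ring[if (pos == m) 1L else pos + 1L]
          k <- bond_between(mol, i, j)
          if (!is.na(k)) mol$bonds$aromatic[k] <- TRUE
        }
      }
    }
  }
  mol$atoms$aromatic <- atom_ar
  mol
}

# sp assignment: triple bond or two doubles -> "sp"; aromatic or one double
# -> "sp2"; everything else -> "sp3".  Terminal atoms (H, halogens) get
# "sp3" nominally; only carbon hybridization is consumed downstream.
assign_hybridization <- function(mol) {
  n <- n_atoms(mol)
  hyb <- rep("sp3", n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(n)) {
      ks <- mol$bond_idx[[i]]
      if (!length(ks)) next
      ords <- mol$bonds$order[ks]
      if (any(ords == 3L) || sum(ords == 2L) >= 2L) hyb[i] <- "sp"
      else if (mol$atoms$aromatic[i] || any(ords == 2L)) hyb[i] <- "sp2"
    }
  }
  mol$atoms$hyb <- hyb
  mol
}

#' Keep only the largest organic fragment of a molecule
#'
#' Salts and co-crystallized fragments are stripped before element filtering:
#' metabolism concerns the parent compound.  The largest fragment is the one
#' with the most heavy atoms (ties: the one containing the lowest source
#' index).
#'
#' @param mol an [mmrs_mol].
#' @return the molecule restricted to its largest connected component, with
#'   source indices preserved.
#' @export
largest_fragment <- function(mol) {
  nf <- count_fragments(mol)
  if (nf <= 1L) return(mol)
  memb <- attr(nf, "membership")
  heavy <- tabulate(memb[mol$atoms$element != "H"], nbins = nf)
  keep_comp <- which.max(heavy)
  keep <- which(memb == keep_comp)
  subset_mol(mol, keep)
}

subset_mol <- function(mol, keep) {
  remap <- integer(n_atoms(mol)); remap[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[b$a %in% keep & b$b %in% keep, , drop = FALSE]
  b$a <- remap[b$a]; b$b <- remap[b$b]
  out <- structure(list(
    mol_id = mol$mol_id,
    atoms = mol$atoms[keep, c("element", "charge", "src"), drop = FALSE],
    bonds = b[, c("a", "b", "order", "aromatic"), drop = FALSE]
  ), class = "mmrs_mol")
  rownames(out$atoms) <- NULL; rownames(out$bonds) <- NULL
  rebuild_mol(out)
}

#' @export
print.mmrs_mol <- function(x, ...) {
  cat(sprintf("<mmrs_mol '%s': %d atoms (%d heavy), %d bonds, %d fragment(s)>\n",
              x$mol_id, n_atoms(x), length(heavy_atoms(x)), nrow(x$bonds),
              x$n_fragments))
  invisible(x)
}

#' @export
format.mmrs_mol <- function(x, ...) {
  sprintf("<mmrs_mol '%s'>", x$mol_id)
}

# map a 1-based source-file atom index to the current internal index
src_to_internal <- function(mol, src_idx) {
  match(src_idx, mol$atoms$src)
}
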