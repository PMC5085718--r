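#' @title Synthetic molecule libraries with planted SOM rules
#'
#' @description The generator assembles small drug-like toy molecules (at
#' most ~15 heavy atoms) from a fixed fragment grammar over the ten
#' permitted elements: a benzene core with 1-3 substituents (ethers,
#' amines, alkyl chains, halogens) for 85% of molecules, small acyclic
#' amines/ethers/alkanes for the rest.  Positive sites of metabolism are
#' planted by deterministic, automorphism-invariant structural rules that
#' are expressible in the package's own descriptor channels, so a perfect
#' classifier exists (ceiling accuracy 1):
#'
#' * type I: a C-H is positive iff its carbon is benzylic;
#' * type II: an aromatic C-H is positive iff the ring carbon is ortho to
#'   an O substituent (visible through the neighbor-charge channel);
#' * type III: a C-N bond is positive iff the nitrogen has at least two
#'   carbon neighbors and the alpha carbon is a terminal methyl;
#' * type IV: a C-O bond is positive iff it is an aryl-methyl ether.
#'
#' Every molecule is assigned 1-3 of the three isozymes uniformly; planted
#' sites are annotated for each assigned enzyme (the rules are
#' enzyme-independent by construction).  All other pattern-matching bonds
#' stay unlabeled, so unlabeled records are true negatives by construction
#' and the negatives-screening stage has a known ground truth.
#' @name synthetic
NULL

# substituent grammar: branch SMILES, heavy atoms in emission order,
# whether the fragment starts with an aryl O, and the planted positives as
# (offset_a, offset_b, type) relative to the fragment base index
# (offset_b = 0 encodes "any hydrogen of offset_a")
toy_substituents <- function() {
  list(
    OMe   = list(smi = "OC",     atoms = c("O", "C"), o_sub = TRUE,  w = 0.22,
                 som = list(c(2L, 1L, 4L))),                    # IV: ArO-CH3
    OEt   = list(smi = "OCC",    atoms = c("O", "C", "C"), o_sub = TRUE, w = 0.08,
                 som = list()),
    Me    = list(smi = "C",      atoms = "C", o_sub = FALSE, w = 0.12,
                 som = list(c(1L, 0L, 1L))),                    # I: benzylic
    Et    = list(smi = "CC",     atoms = c("C", "C"), o_sub = FALSE, w = 0.10,
                 som = list(c(1L, 0L, 1L))),
    Pr    = list(smi = "CCC",    atoms = c("C", "C", "C"), o_sub = FALSE, w = 0.05,
                 som = list(c(1L, 0L, 1L))),
    CNMe2 = list(smi = "CN(C)C", atoms = c("C", "N", "C", "C"), o_sub = FALSE, w = 0.12,
                 som = list(c(1L, 0L, 1L),                      # benzylic CH2
                            c(3L, 2L, 3L), c(4L, 2L, 3L))),     # III: N-CH3
    NMe2  = list(smi = "N(C)C",  atoms = c("N", "C", "C"), o_sub = FALSE, w = 0.08,
                 som = list(c(2L, 1L, 3L), c(3L, 1L, 3L))),
    NHMe  = list(smi = "NC",     atoms = c("N", "C"), o_sub = FALSE, w = 0.06,
                 som = list(c(2L, 1L, 3L))),
    Cl    = list(smi = "Cl",     atoms = "Cl", o_sub = FALSE, w = 0.05,
                 som = list()),
    F     = list(smi = "F",      atoms = "F", o_sub = FALSE, w = 0.04,
                 som = list()),
    CH2OH = list(smi = "CO",     atoms = c("C", "O"), o_sub = FALSE, w = 0.04,
                 som = list(c(1L, 0L, 1L))),
    CH2OMe = list(smi = "COC",   atoms = c("C", "O", "C"), o_sub = FALSE, w = 0.04,
                 som = list(c(1L, 0L, 1L))))
}

# acyclic cores: full SMILES, heavy-atom count, planted positives as
# absolute (atom_a, atom_b, type)
toy_acyclics <- function() {
  list(
    list(smi = "CCN(C)CC", n = 6L, som = list(c(4L, 3L, 3L))),
    list(smi = "CCOCC",    n = 5L, som = list()),
    list(smi = "CCCCCC",   n = 6L, som = list()),
    list(smi = "CN(C)CCOC", n = 7L, som = list(c(1L, 2L, 3L), c(3L, 2L, 3L))),
    list(smi = "CC(C)OCC", n = 6L, som = list()),
    list(smi = "CCNCC",    n = 5L, som = list()))
}

ROMAN <- c("I", "II", "III", "IV")

#' Generate a toy molecule library with planted SOM annotations
#'
#' @param n_molecules library size (>= 10).
#' @param seed RNG seed; the same seed reproduces the library exactly.
#' @param p_aromatic fraction of molecules built on a benzene core
#'   (default 0.85).
#' @return list with `smiles` (data.frame: smiles, mol_id), `annotations`
#'   (data.frame: mol_id, atom_a, atom_b, enzyme, reaction_type) and
#'   `registry` (data.frame: mol_id, enzyme).
#' @export
make_toy_library <- function(n_molecules, seed = 0L, p_aromatic = 0.85) {
  if (n_molecules < 10L) stop("n_molecules must be at least 10")
  set.seed(seed)
  subs <- toy_substituents()
  sub_w <- vapply(subs, `[[`, 0, "w")
  acyc <- toy_acyclics()
  smi_rows <- list(); ann_rows <- list(); reg_rows <- list()
  for (i in seq_len(n_molecules)) {
    id <- sprintf("toy%04d", i)
    enzymes <- sample(ENZYMES, sample(1:3, 1))
    if (stats::runif(1) < p_aromatic) {
      gen <- build_benzene_mol(subs, sub_w)
    } else {
      a <- acyc[[sample(length(acyc), 1)]]
      gen <- list(smi = a$smi, som = a$som)
    }
    smi_rows[[i]] <- data.frame(smiles = gen$smi, mol_id = id)
    reg_rows[[i]] <- data.frame(mol_id = id, enzyme = enzymes)
    if (length(gen$som)) {
      som <- do.call(rbind, lapply(gen$som, function(s)
        data.frame(atom_a = s[1], atom_b = s[2],
                   reaction_type = ROMAN[s[3]])))
      som <- unique(som)
      ann_rows[[i]] <- merge(data.frame(mol_id = id, enzyme = enzymes),
                             cbind(mol_id = id, som))
    }
  }
  annotations <- do.call(rbind, ann_rows)
  annotations <- annotations[c("mol_id", "atom_a", "atom_b", "enzyme",
                               "reaction_type")]
  rownames(annotations) <- NULL
  list(smiles = do.call(rbind, smi_rows),
       annotations = annotations,
       registry = do.call(rbind, reg_rows))
}

# assemble one substituted benzene; tracks heavy-atom emission order so the
# planted annotations carry the same indices the SMILES parser will assign
build_benzene_mol <- function(subs, sub_w) {
  n_sub <- sample(1:3, 1)
  positions <- sort(sample(2:6, n_sub))
  chosen <- sample(names(subs), n_sub, replace = TRUE, prob = sub_w)
  frag_at <- stats::setNames(as.list(chosen), positions)
  counter <- 0L
  ring_idx <- integer(6)
  smi <- ""
  som <- list()
  o_positions <- integer(0)
  for (p in 1:6) {
    counter <- counter + 1L
    ring_idx[p] <- counter
    smi <- paste0(smi, if (p == 1L || p == 6L) "c1" else "c")
    fp <- frag_at[[as.character(p)]]
    if (!is.null(fp)) {
      fr <- subs[[fp]]
      base <- counter
      counter <- counter + length(fr$atoms)
      smi <- paste0(smi, if (p < 6L) paste0("(", fr$smi, ")") else fr$smi)
      if (fr$o_sub) o_positions <- c(o_positions, p)
      for (s in fr$som)
        som[[length(som) + 1L]] <- c(base + s[1],
                                     if (s[2] == 0L) 0L else base + s[2],
                                     s[3])
    }
  }
  # planted type II: unsubstituted ring carbons ortho to an O substituent
  occupied <- as.integer(names(frag_at))
  for (p in o_positions) {
    for (q in c(p %% 6L + 1L, (p + 4L) %% 6L + 1L)) {
      if (!(q %in% occupied))
        som[[length(som) + 1L]] <- c(ring_idx[q], 0L, 2L)
    }
  }
  list(smi = smi, som = som)
}

#' Write a toy library to disk
#'
#' Emits `library.smi` (SMILES + id), `som.tsv` (annotations) and
#' `enzymes.tsv` (substrate registry).
#'
#' @param lib result of [make_toy_library].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(lib$smiles, file.path(dir, "library.smi"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(lib$annotations, file.path(dir, "som.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lib$registry, file.path(dir, "enzymes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Abstract feature table with planted informative columns
#'
#' Builds a 59-column feature matrix shaped like an MMRS descriptor table:
#' `n_informative` of the 56 descriptor columns are drawn from
#' class-conditional Gaussians whose means differ by `effect` (in units of
#' the within-class standard deviation `noise`), the remaining descriptor
#' columns are standard Gaussian noise, and the three enzyme columns are a
#' random one-hot block.  Labels are balanced to within one record.
#'
#' @param n rows.
#' @param n_informative number of informative descriptor columns (<= 56).
#' @param effect mean separation between classes on informative columns.
#' @param noise within-class standard deviation (default 1).
#' @param seed RNG seed.
#' @return list with `X` (matrix, canonical column names), `y` (factor
#'   neg/pos) and `informative` (sorted column ids).
#' @export
make_feature_table <- function(n, n_informative = 5L, effect = 3,
                               noise = 1, seed = 0L) {
  if (n_informative > 56L) stop("n_informative must be <= 56")
  set.seed(seed)
  y <- factor(rep_len(c("pos", "neg"), n), levels = c("neg", "pos"))
  informative <- sort(sample(56L, n_informative))
  X <- matrix(stats::rnorm(n * 56L, sd = 1), n, 56L)
  shift <- ifelse(y == "pos", effect / 2, -effect / 2)
  for (j in informative)
    X[, j] <- stats::rnorm(n, mean = shift, sd = noise)
  enz <- t(vapply(sample(ENZYMES, n, replace = TRUE), encode_enzyme,
                  numeric(3)))
  X <- cbind(X, enz)
  colnames(X) <- mmrs_feature_names()
  rownames(X) <- NULL
  list(X = X, y = y, informative = informative)
}
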