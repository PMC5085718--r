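#' @title MMRS candidate enumeration and labeling
#'
#' @description A microsomal metabolic reaction system (MMRS) is one
#' candidate bond of a substrate paired with the CYP isozyme considered to
#' act on it.  Four biotransformations are covered, each with a fixed bond
#' pattern; the oriented pair (A, B) always puts the reacting carbon in A:
#'
#' * `I`  aliphatic C-hydroxylation: every H bonded to a non-aromatic carbon
#'   (A = C, B = H);
#' * `II` aromatic C-hydroxylation: every H bonded to an aromatic carbon;
#' * `III` N-dealkylation: every single, non-aromatic C-N bond whose carbon
#'   is sp3 and bears at least one H (A = the dealkylatable alpha carbon,
#'   B = N);
#' * `IV` O-dealkylation: as III with B = O, and the oxygen must have a
#'   second heavy neighbor (ether/ester type; hydroxyl C-O bonds cannot be
#'   O-dealkylated).
#'
#' Patterns I and II are disjoint by the aromatic flag.
#' @name mmrs_patterns
NULL

#' Enumerate candidate bonds for one biotransformation
#'
#' @param mol an [mmrs_mol] that passed [filter_elements].
#' @param reaction_type one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param exclude_amide_n for pattern III, drop bonds whose nitrogen is an
#'   amide nitrogen (default `FALSE`: amide alpha carbons stay candidates).
#' @return data.frame with columns `a` (carbon) and `b` (partner atom),
#'   internal 1-based indices; zero rows when nothing matches.
#' @export
enumerate_candidates <- function(mol, reaction_type,
                                 exclude_amide_n = FALSE) {
  reaction_type <- match.arg(reaction_type, REACTION_TYPES)
  el <- mol$atoms$element
  ar <- mol$atoms$aromatic
  hyb <- mol$atoms$hyb
  res <- list()
  if (reaction_type %in% c("I", "II")) {
    want_aromatic <- reaction_type == "II"
    for (h in which(el == "H")) {
      nb <- mol$adj[[h]]
      if (length(nb) != 1L) next
      c_at <- nb[1]
      if (el[c_at] != "C") next
      if (ar[c_at] == want_aromatic)
        res[[length(res) + 1L]] <- c(c_at, h)
    }
  } else {
    partner_el <- if (reaction_type == "III") "N" else "O"
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] != 1L || mol$bonds$aromatic[k]) next
      i <- mol$bonds$a[k]; j <- mol$bonds$b[k]
      if (el[i] == partner_el && el[j] == "C") { tmp <- i; i <- j; j <- tmp }
      if (!(el[i] == "C" && el[j] == partner_el)) next
      if (hyb[i] != "sp3" || ar[i]) next
      has_h <- any(el[mol$adj[[i]]] == "H")
      if (!has_h) next
      if (reaction_type == "IV") {
        heavy_nb <- sum(el[mol$adj[[j]]] != "H")
        if (heavy_nb < 2L) next
      }
      if (reaction_type == "III" && exclude_amide_n && is_amide_n(mol, j)) next
      res[[length(res) + 1L]] <- c(i, j)
    }
  }
  if (!length(res))
    return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, res)
  df <- data.frame(a = m[, 1], b = m[, 2])
  df[order(df$a, df$b), , drop = FALSE]
}

is_amide_n <- function(mol, n_idx) {
  for (c_at in mol$adj[[n_idx]]) {
    if (mol$atoms$element[c_at] != "C") next
    ks <- mol$bond_idx[[c_at]]
    for (idx in seq_along(ks)) {
      w <- mol$adj[[c_at]][idx]
      if (mol$atoms$element[w] == "O" && mol$bonds$order[ks[idx]] == 2L)
        return(TRUE)
    }
  }
  FALSE
}

# ---- symmetry --------------------------------------------------------------

# Generators of the automorphism group of the molecular graph, respecting
# element, formal charge and bond kind (single / double / triple /
# aromatic; all aromatic bonds are mutually equivalent regardless of the
# kekulized orders underneath).  Bond kinds other than single are encoded
# by an auxiliary colored vertex subdividing the edge, since the BLISS
# backend colors vertices only.  Returns a list of permutations of the
# atom indices.
automorphism_generators <- function(mol) {
  n <- n_atoms(mol)
  el_codes <- match(mol$atoms$element, PERMITTED_ELEMENTS)
  colors <- el_codes * 16L + (mol$atoms$charge + 4L)
  edges <- integer(0)
  extra_colors <- integer(0)
  nv <- n
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    kind <- if (mol$bonds$aromatic[k]) 5L else mol$bonds$order[k]
    if (kind > 1L) {
      nv <- nv + 1L
      edges <- c(edges, a, nv, nv, b)
      extra_colors <- c(extra_colors, 1000L + kind)
    } else {
      edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  all_colors <- c(colors, extra_colors)
  gens <- igraph::automorphism_group(g, colors = as.integer(all_colors))
  lapply(gens, function(p) as.integer(p)[seq_len(n)])
}

# Orbit partition of a set of ordered atom pairs under the automorphism
# group: closure of each pair under the generators.
pair_orbits <- function(pairs, gens) {
  npair <- nrow(pairs)
  key <- paste(pairs$a, pairs$b)
  class_id <- integer(npair)
  cur <- 0L
  lookup <- seq_len(npair); names(lookup) <- key
  for (i in seq_len(npair)) {
    if (class_id[i] != 0L) next
    cur <- cur + 1L
    frontier <- i; class_id[i] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (idx in frontier) {
        for (p in gens) {
          ka <- p[pairs$a[idx]]; kb <- p[pairs$b[idx]]
          j <- lookup[paste(ka, kb)]
          if (!is.na(j) && class_id[j] == 0L) {
            class_id[j] <- cur; nxt <- c(nxt, j)
          }
        }
      }
      frontier <- nxt
    }
  }
  class_id
}

#' Collapse symmetry-equivalent candidate bonds
#'
#' Two candidate bonds are equivalent when a graph automorphism of the
#' molecule (respecting element, formal charge and bond order) maps one
#' oriented pair onto the other, e.g. the three C-H bonds of a methyl group
#' or the six of benzene.  One representative (the lowest (a, b) index pair)
#' is kept per class.
#'
#' @param candidates data.frame from [enumerate_candidates].
#' @param mol the molecule.
#' @return list with `representatives` (data.frame a, b, symmetry_class,
#'   class_size) and `all` (the input candidates with their
#'   `symmetry_class`), plus the generator list in attribute `generators`.
#' @export
collapse_symmetry <- function(candidates, mol) {
  if (!nrow(candidates)) {
    reps <- data.frame(a = integer(0), b = integer(0),
                       symmetry_class = integer(0), class_size = integer(0))
    return(list(representatives = reps,
                all = cbind(candidates, symmetry_class = integer(0))))
  }
  gens <- automorphism_generators(mol)
  cls <- pair_orbits(candidates, gens)
  all_df <- cbind(candidates, symmetry_class = cls)
  reps <- do.call(rbind, lapply(split(all_df, cls), function(d) {
    d <- d[order(d$a, d$b), , drop = FALSE]
    data.frame(a = d$a[1], b = d$b[1], symmetry_class = d$symmetry_class[1],
               class_size = nrow(d))
  }))
  reps <- reps[order(reps$a, reps$b), , drop = FALSE]
  rownames(reps) <- NULL
  structure(list(representatives = reps, all = all_df), generators = gens)
}

# ---- labeling --------------------------------------------------------------

#' Label MMRS candidates of one molecule as positive or unlabeled
#'
#' One MMRS is produced per (symmetry class x enzyme acting on the
#' molecule).  A class is positive for an enzyme when an annotation of that
#' molecule/enzyme/reaction type falls into the class (any member bond, so
#' annotating one hydrogen of a methyl group marks the whole class); all
#' other MMRS are unlabeled.  Negative labels are only ever assigned later
#' by the screening stage.
#'
#' @param mol the molecule.
#' @param collapsed result of [collapse_symmetry].
#' @param reaction_type the pattern the candidates were enumerated for.
#' @param annotations annotation data.frame ([read_som_annotations]),
#'   already restricted or not to this molecule.
#' @param enzymes character vector of enzymes acting on this molecule.
#' @return data.frame of MMRS records: mol_id, atom_a, atom_b (source
#'   indices), enzyme, reaction_type, symmetry_class, label.
#' @export
label_mmrs <- function(mol, collapsed, reaction_type, annotations, enzymes) {
  reps <- collapsed$representatives
  if (!nrow(reps) || !length(enzymes)) {
    return(data.frame(mol_id = character(0), atom_a = integer(0),
                      atom_b = integer(0), enzyme = character(0),
                      reaction_type = character(0),
                      symmetry_class = integer(0), label = character(0)))
  }
  ann <- annotations[annotations$mol_id == mol$mol_id &
                     annotations$reaction_type == reaction_type, ,
                     drop = FALSE]
  pos_classes <- list()  # enzyme -> set of classes
  if (nrow(ann)) {
    for (r in seq_len(nrow(ann))) {
      pair <- resolve_annotation_pair(mol, ann$atom_a[r], ann$atom_b[r],
                                      reaction_type)
      hit <- which(collapsed$all$a == pair[1] & collapsed$all$b == pair[2])
      if (!length(hit))
        stop("annotation (", ann$atom_a[r], ",", ann$atom_b[r], ") type ",
             reaction_type, " of molecule '", mol$mol_id,
             "' matches no enumerated candidate (pattern mismatch?)")
      cls <- collapsed$all$symmetry_class[hit[1]]
      e <- ann$enzyme[r]
      pos_classes[[e]] <- union(pos_classes[[e]], cls)
    }
  }
  out <- expand.grid(idx = seq_len(nrow(reps)), enzyme = enzymes,
                     stringsAsFactors = FALSE)
  data.frame(
    mol_id = mol$mol_id,
    atom_a = mol$atoms$src[reps$a[out$idx]],
    atom_b = mol$atoms$src[reps$b[out$idx]],
    enzyme = out$enzyme,
    reaction_type = reaction_type,
    symmetry_class = reps$symmetry_class[out$idx],
    label = ifelse(mapply(function(i, e)
      reps$symmetry_class[i] %in% pos_classes[[e]], out$idx, out$enzyme),
      "positive", "unlabeled"),
    stringsAsFactors = FALSE)
}

# Normalize an annotated bond to the internal oriented (A = carbon, B =
# partner) pair.  atom indices are source-file indices; atom_b = 0 for C-H
# sites means "any hydrogen of atom_a" (first H is taken; symmetry closure
# makes the choice immaterial).
resolve_annotation_pair <- function(mol, atom_a, atom_b, reaction_type) {
  a <- src_to_internal(mol, atom_a)
  if (is.na(a)) stop("annotation atom ", atom_a, " not in molecule '",
                     mol$mol_id, "'")
  if (atom_b == 0L) {
    if (!(reaction_type %in% c("I", "II")))
      stop("atom_b = 0 is only valid for C-H reaction types I/II")
    hs <- mol$adj[[a]][mol$atoms$element[mol$adj[[a]]] == "H"]
    if (!length(hs)) stop("annotation atom ", atom_a, " of '", mol$mol_id,
                          "' bears no hydrogen")
    return(c(a, hs[1]))
  }
  b <- src_to_internal(mol, atom_b)
  if (is.na(b)) stop("annotation atom ", atom_b, " not in molecule '",
                     mol$mol_id, "'")
  if (is.na(bond_between(mol, a, b)))
    stop("annotated pair (", atom_a, ",", atom_b, ") is not a bond in '",
         mol$mol_id, "'")
  # orient: carbon first
  if (mol$atoms$element[a] != "C" && mol$atoms$element[b] == "C") {
    tmp <- a; a <- b; b <- tmp
  }
  c(a, b)
}

#' Extract labeled, descriptor-annotated MMRS records from a library
#'
#' Runs the full extraction for every molecule: pH 7.4 protonation,
#' candidate enumeration for all four patterns, symmetry collapsing,
#' positive/unlabeled labeling against the annotations, and descriptor
#' computation.
#'
#' @param mols list of filtered [mmrs_mol].
#' @param annotations annotation data.frame.
#' @param registry optional data.frame (mol_id, enzyme); defaults to the
#'   enzymes each molecule carries in `annotations`.
#' @param exclude_amide_n see [enumerate_candidates].
#' @return list with `records` (data.frame of MMRS) and `vectors` (numeric
#'   matrix, one descriptor row per record).
#' @export
extract_mmrs <- function(mols, annotations, registry = NULL,
                         exclude_amide_n = FALSE) {
  if (is.null(registry))
    registry <- unique(annotations[c("mol_id", "enzyme")])
  rec_list <- list(); vec_list <- list()
  for (mol in mols) {
    mol <- protonate_ph74(mol)
    enzymes <- registry$enzyme[registry$mol_id == mol$mol_id]
    if (!length(enzymes)) next
    props <- compute_atomic_properties(mol)
    for (rt in REACTION_TYPES) {
      cands <- enumerate_candidates(mol, rt, exclude_amide_n = exclude_amide_n)
      collapsed <- collapse_symmetry(cands, mol)
      recs <- label_mmrs(mol, collapsed, rt, annotations, enzymes)
      if (!nrow(recs)) next
      reps <- collapsed$representatives
      base_vecs <- t(vapply(seq_len(nrow(reps)), function(i)
        descriptor_values(mol, props, reps$a[i], reps$b[i]),
        numeric(56)))
      rows <- match(paste(recs$atom_a, recs$atom_b),
                    paste(mol$atoms$src[reps$a], mol$atoms$src[reps$b]))
      vecs <- cbind(base_vecs[rows, , drop = FALSE],
                    t(vapply(recs$enzyme, encode_enzyme, numeric(3))))
      colnames(vecs) <- mmrs_feature_names()
      rec_list[[length(rec_list) + 1L]] <- recs
      vec_list[[length(vec_list) + 1L]] <- vecs
    }
  }
  if (!length(rec_list))
    stop("no MMRS records extracted (no molecule matched the registry?)")
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  vectors <- do.call(rbind, vec_list)
  rownames(vectors) <- NULL
  list(records = records, vectors = vectors)
}

#' Partition MMRS records into the four per-reaction datasets
#'
#' @param mmrs result of [extract_mmrs] (list with records and vectors).
#' @return named list of four datasets, each a list with `reaction_type`,
#'   `records`, `vectors` and `counts` (positive/unlabeled/negative).
#' @export
build_reaction_datasets <- function(mmrs) {
  out <- lapply(REACTION_TYPES, function(rt) {
    sel <- mmrs$records$reaction_type == rt
    recs <- mmrs$records[sel, , drop = FALSE]
    list(reaction_type = rt,
         records = recs,
         vectors = mmrs$vectors[sel, , drop = FALSE],
         counts = c(positive = sum(recs$label == "positive"),
                    unlabeled = sum(recs$label == "unlabeled"),
                    negative = sum(recs$label == "negative")))
  })
  names(out) <- REACTION_TYPES
  out
}

REACTION_NAMES <- c(
  I = "Aliphatic C-hydroxylation",
  II = "Aromatic C-hydroxylation",
  III = "N-dealkylation",
  IV = "O-dealkylation")

#' Summarize the site-of-metabolism distribution over reaction types
#'
#' @param x either an annotation data.frame (counted by `reaction_type`) or
#'   a named integer vector of counts per reaction type.
#' @return data.frame with columns `reaction_type`, `count`, `percentage`
#'   (percentage of the total, rounded to one decimal as conventionally
#'   printed).
#' @export
summarize_som_distribution <- function(x) {
  if (is.data.frame(x)) {
    if (!nrow(x)) stop("no annotations to summarize")
    counts <- table(x$reaction_type)
  } else {
    if (!length(x) || sum(x) == 0) stop("no counts to summarize")
    counts <- x
    if (is.null(names(counts)))
      names(counts) <- paste0("type", seq_along(counts))
  }
  total <- sum(counts)
  data.frame(reaction_type = names(counts),
             count = as.integer(counts),
             percentage = round(100 * as.numeric(counts) / total, 1),
             stringsAsFactors = FALSE)
}
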