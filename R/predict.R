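#' Predict per-bond metabolism calls for one molecule
#'
#' Applies the fitted per-reaction models to a new molecule under a given
#' isozyme: candidates are enumerated and collapsed with the same pattern
#' and symmetry rules as in training, descriptors are computed under the
#' same pH 7.4 and bond-orientation conventions, and each bundle scores
#' its reaction type on its manifest feature subset.  Calls for the same
#' bond under different enzymes are independent (the enzyme indicators are
#' part of the feature vector).  A bond matching several patterns receives
#' one call per applicable reaction type; no arbitration is attempted.
#'
#' @param mol an [mmrs_mol] that passed [filter_elements].
#' @param enzyme isozyme name (CYP3A4, CYP2D6 or CYP2C9).
#' @param bundles named list of fitted bundles (names among I, II, III,
#'   IV); reactions without a bundle are skipped.
#' @param threshold probability cut for a positive call (default 0.5).
#' @param exclude_amide_n see [enumerate_candidates].
#' @return data.frame: mol_id, atom_a, atom_b (source indices), enzyme,
#'   reaction_type, probability, call.
#' @export
predict_molecule <- function(mol, enzyme, bundles, threshold = 0.5,
                             exclude_amide_n = FALSE) {
  enzyme <- normalize_enzyme(enzyme)
  if (!(enzyme %in% ENZYMES)) stop("enzyme not in training enumeration: ",
                                   enzyme)
  mol <- protonate_ph74(mol)
  props <- compute_atomic_properties(mol)
  enc <- encode_enzyme(enzyme)
  out <- list()
  for (rt in intersect(REACTION_TYPES, names(bundles))) {
    bundle <- bundles[[rt]]
    cands <- enumerate_candidates(mol, rt, exclude_amide_n = exclude_amide_n)
    collapsed <- collapse_symmetry(cands, mol)
    reps <- collapsed$representatives
    if (!nrow(reps)) next
    vecs <- t(vapply(seq_len(nrow(reps)), function(i)
      descriptor_values(mol, props, reps$a[i], reps$b[i]), numeric(56)))
    vecs <- cbind(vecs, matrix(enc, nrow(reps), 3, byrow = TRUE))
    colnames(vecs) <- mmrs_feature_names()
    feats <- bundle$manifest$feature_labels
    prob <- predict_classifier(bundle$model, vecs[, feats, drop = FALSE])
    out[[rt]] <- data.frame(
      mol_id = mol$mol_id,
      atom_a = mol$atoms$src[reps$a],
      atom_b = mol$atoms$src[reps$b],
      enzyme = enzyme,
      reaction_type = rt,
      probability = prob,
      call = ifelse(prob >= threshold, "positive", "negative"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mol_id = character(0), atom_a = integer(0),
                      atom_b = integer(0), enzyme = character(0),
                      reaction_type = character(0), probability = numeric(0),
                      call = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate the fitted models on an annotated external set
#'
#' Every enumerated MMRS of every (molecule, enzyme) pair in the registry
#' is called by the models and compared with its annotation-derived label
#' (positive where annotated, negative otherwise).  Accuracy is
#' micro-averaged over all MMRS, with a per-reaction breakdown.
#'
#' @param mols list of filtered molecules.
#' @param annotations annotation data.frame.
#' @param bundles named list of fitted bundles (I..IV).
#' @param registry optional substrate registry (mol_id, enzyme); defaults
#'   to the pairs present in `annotations`.
#' @param threshold probability cut (default 0.5).
#' @return list with `accuracy`, `n_correct`, `n_total`, `by_reaction`
#'   (data.frame) and `calls` (per-MMRS data.frame incl. truth).
#' @export
external_evaluate <- function(mols, annotations, bundles, registry = NULL,
                              threshold = 0.5) {
  if (is.null(registry))
    registry <- unique(annotations[c("mol_id", "enzyme")])
  ext <- extract_mmrs(mols, annotations, registry)
  calls <- list()
  for (mol in mols) {
    enzymes <- registry$enzyme[registry$mol_id == mol$mol_id]
    for (e in enzymes)
      calls[[paste(mol$mol_id, e)]] <-
        predict_molecule(mol, e, bundles, threshold = threshold)
  }
  calls <- do.call(rbind, calls)
  key <- function(d) paste(d$mol_id, d$atom_a, d$atom_b, d$enzyme,
                           d$reaction_type)
  truth <- ext$records
  m <- match(key(calls), key(truth))
  calls$truth <- ifelse(is.na(m), NA,
                        ifelse(truth$label[m] == "positive",
                               "positive", "negative"))
  calls <- calls[!is.na(calls$truth), , drop = FALSE]
  calls$correct <- calls$call == calls$truth
  by_rt <- do.call(rbind, lapply(split(calls, calls$reaction_type),
    function(d) data.frame(reaction_type = d$reaction_type[1],
                           n = nrow(d), n_correct = sum(d$correct),
                           accuracy = mean(d$correct))))
  rownames(by_rt) <- NULL
  list(accuracy = mean(calls$correct),
       n_correct = sum(calls$correct),
       n_total = nrow(calls),
       by_reaction = by_rt,
       calls = calls)
}
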