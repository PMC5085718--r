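#' @title Negatives screening
#'
#' @description Experimental metabolism data contains false negatives:
#' bonds never reported as sites of metabolism may simply never have been
#' probed.  Instead of treating every unlabeled MMRS as a negative, the
#' eight roster classifiers are trained to discriminate positive from
#' unlabeled records under stratified 10-fold cross-validation; each
#' unlabeled record receives one vote from every classifier whose
#' out-of-fold prediction calls it unlabeled.  Records with more than
#' `vote_threshold` (default 5, i.e. at least 6 of 8) votes are promoted
#' to reliable negatives; the rest of the unlabeled pool is discarded
#' before modeling.
#' @name screening
NULL

#' Screen reliable negatives out of the unlabeled MMRS pool
#'
#' @param dataset one reaction dataset from [build_reaction_datasets]
#'   (list with `records` and `vectors`), or any list with those fields
#'   and a `label` column containing `positive`/`unlabeled`.
#' @param seed RNG seed (folds and classifier seeds derive from it).
#' @param vote_threshold strict vote cut: negatives need votes
#'   `> vote_threshold` (default 5).
#' @param folds CV folds (default 10; reduced with a message when a class
#'   is smaller).
#' @param classifiers roster members to use (default all 8).
#' @return list with `scores` (data.frame: row id, per-classifier
#'   verdicts, votes, decision) and `negatives` (integer row indices into
#'   `dataset$records` promoted to negative).
#' @export
screen_negatives <- function(dataset, seed = 1L, vote_threshold = 5L,
                             folds = 10L,
                             classifiers = classifier_roster()) {
  recs <- dataset$records
  X <- dataset$vectors
  if (!nrow(recs)) stop("empty dataset")
  y <- factor(ifelse(recs$label == "positive", "pos", "neg"),
              levels = c("neg", "pos"))     # "neg" here means unlabeled
  n_pos <- sum(y == "pos"); n_unl <- sum(y == "neg")
  if (n_pos < 2L || n_unl < 2L)
    stop("need at least 2 positive and 2 unlabeled records to screen")
  fold <- stratified_folds(y, folds, seed)
  unl <- which(y == "neg")
  verdicts <- matrix(NA_integer_, length(unl), length(classifiers),
                     dimnames = list(NULL, classifiers))
  abstained <- 0L
  for (ci in seq_along(classifiers)) {
    cl <- classifiers[ci]
    p <- tryCatch(
      cv_predict(X, y, cl, folds = fold, seed = seed + ci),
      error = function(e) {
        warning("classifier ", cl, " failed to fit and abstains: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(p)) {
      abstained <- abstained + 1L
      if (abstained > 2L)
        stop("more than two screening classifiers failed; aborting")
      verdicts[, ci] <- 0L
    } else {
      # one vote when the model predicts the record as unlabeled
      verdicts[, ci] <- as.integer(p[unl] < 0.5)
    }
  }
  votes <- rowSums(verdicts)
  decision <- votes > vote_threshold
  scores <- data.frame(row = unl, verdicts, votes = votes,
                       decision = ifelse(decision, "negative", "discard"))
  list(scores = scores, negatives = unl[decision])
}

#' Build the final modeling set with a stratified 4:1 split
#'
#' Unlabeled records not promoted to negative are discarded; positives and
#' negatives are split 4:1 into training and test parts, stratified by
#' label (the positive fraction of both parts matches to within one
#' record per class).
#'
#' @param dataset one reaction dataset (records + vectors).
#' @param negatives row indices from [screen_negatives].
#' @param seed RNG seed for the shuffle.
#' @param ratio train:test ratio (default 4).
#' @return list with `train` and `test` (each: `records`, `vectors`),
#'   `reaction_type`, `split_seed`.
#' @export
build_modeling_set <- function(dataset, negatives, seed = 1L, ratio = 4L) {
  recs <- dataset$records
  recs$label[negatives] <- "negative"
  keep <- which(recs$label %in% c("positive", "negative"))
  recs <- recs[keep, , drop = FALSE]
  X <- dataset$vectors[keep, , drop = FALSE]
  n_pos <- sum(recs$label == "positive")
  n_neg <- sum(recs$label == "negative")
  if (n_pos < 2L || n_neg < 2L)
    stop("need at least 2 positives and 2 negatives after screening (have ",
         n_pos, " / ", n_neg, ")")
  set.seed(seed)
  test_idx <- integer(0)
  for (lab in c("positive", "negative")) {
    idx <- sample(which(recs$label == lab))
    n_test <- round(length(idx) / (ratio + 1L))
    test_idx <- c(test_idx, idx[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(recs)), test_idx)
  list(reaction_type = dataset$reaction_type,
       split_seed = seed,
       train = list(records = recs[train_idx, , drop = FALSE],
                    vectors = X[train_idx, , drop = FALSE]),
       test = list(records = recs[test_idx, , drop = FALSE],
                   vectors = X[test_idx, , drop = FALSE]))
}
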