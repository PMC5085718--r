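#' Confusion counts
#'
#' @param labels true binary labels (logical, 0/1, or factor with positive
#'   level `"pos"`/`"positive"`/`1`/`TRUE`).
#' @param predictions predicted labels, same encoding.
#' @return named integer vector (TP, TN, FP, FN).
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  y <- as_binary(labels); p <- as_binary(predictions)
  c(TP = sum(y & p), TN = sum(!y & !p),
    FP = sum(!y & p), FN = sum(y & !p))
}

as_binary <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x > 0.5)
  x <- tolower(as.character(x))
  x %in% c("pos", "positive", "1", "true", "yes")
}

#' Sensitivity, specificity, accuracy and balanced accuracy
#'
#' SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/n, BACC = (SE+SP)/2.
#'
#' @param TP,TN,FP,FN non-negative confusion counts (or pass the vector
#'   from [confusion] as `TP`).
#' @return named numeric vector (SE, SP, ACC, BACC).
#' @export
summary_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (length(TP) == 4L && is.null(TN)) {
    TN <- TP[["TN"]]; FP <- TP[["FP"]]; FN <- TP[["FN"]]; TP <- TP[["TP"]]
  }
  n <- TP + TN + FP + FN
  if (n <= 0) stop("empty confusion table")
  if (TP + FN == 0) stop("SE undefined: no positive instances")
  if (TN + FP == 0) stop("SP undefined: no negative instances")
  se <- TP / (TP + FN); sp <- TN / (TN + FP)
  c(SE = se, SP = sp, ACC = (TP + TN) / n, BACC = (se + sp) / 2)
}

#' Area under the ROC curve
#'
#' Computed by the Mann-Whitney rank statistic, P(score+ > score-) +
#' 0.5 P(tie), which equals the trapezoidal area under the ROC curve.
#'
#' @param labels true binary labels.
#' @param scores continuous scores (class probabilities or decision
#'   values), higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  y <- as_binary(labels)
  if (length(y) != length(scores))
    stop("labels and scores differ in length")
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L)
    stop("AUC undefined: one class is absent")
  r <- rank(scores)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a fitted bundle on its modeling set
#'
#' Produces the standard two-row quality report: a seeded stratified
#' 10-fold cross-validation on the training split (the model is refit per
#' fold with the bundle's classifier and feature subset) and a single
#' evaluation of the fitted model on the held-out test split.
#'
#' @param bundle fitted bundle from [fit_final].
#' @param modeling_set result of [build_modeling_set].
#' @param folds CV folds for the training report (default 10).
#' @param seed RNG seed for fold assignment.
#' @param threshold probability cut converting scores to calls (default
#'   0.5).
#' @return data.frame with rows `training`/`test` and columns SE, SP, ACC,
#'   BACC, AUC (fractions; round for display as needed).
#' @export
evaluate_bundle <- function(bundle, modeling_set, folds = 10L, seed = 1L,
                            threshold = 0.5) {
  feats <- bundle$manifest$feature_labels
  if (!all(feats %in% colnames(modeling_set$train$vectors)))
    stop("modeling set lacks features named in the bundle manifest")
  Xtr <- modeling_set$train$vectors[, feats, drop = FALSE]
  ytr <- factor(ifelse(modeling_set$train$records$label == "positive",
                       "pos", "neg"), levels = c("neg", "pos"))
  Xte <- modeling_set$test$vectors[, feats, drop = FALSE]
  yte <- factor(ifelse(modeling_set$test$records$label == "positive",
                       "pos", "neg"), levels = c("neg", "pos"))
  cvp <- cv_predict(Xtr, ytr, bundle$manifest$classifier, folds = folds,
                    seed = seed)
  tr <- report_row(ytr, cvp, threshold)
  tep <- predict_classifier(bundle$model, Xte)
  te <- report_row(yte, tep, threshold)
  out <- rbind(training = tr, test = te)
  as.data.frame(out)
}

report_row <- function(y, prob, threshold) {
  cm <- confusion(y == "pos", prob >= threshold)
  m <- summary_metrics(cm)
  c(m, AUC = roc_auc(y == "pos", prob))
}
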