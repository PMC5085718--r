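#' @title The eight-classifier roster
#'
#' @description Fixed roster used both for negatives screening and for the
#' model-search grid: AdaBoostM1 (50 rounds, decision-stump base as in the
#' classical WEKA configuration, with early stopping at zero or >= 0.5
#' weighted error), Bagging (10 bootstrap
#' bags of 1-nearest-neighbour), BN (Gaussian naive Bayes), IBK
#' (1-nearest-neighbour), J48 (entropy-split decision tree via rpart), KStar
#' (instance-based learner with an exponential distance kernel, global
#' blend 20%), SVM (RBF kernel, C = 1, gamma = 1/d, via e1071; decision
#' values mapped to probabilities by a logistic link), RF (random forest,
#' 100 trees, via ranger).  All stochastic members are seeded.  Features
#' are standardized internally using training-set statistics.
#' @name roster
NULL

#' Names of the eight roster classifiers
#'
#' @return character vector in canonical (tie-break) order.
#' @export
classifier_roster <- function() {
  c("AdaBoostM1", "Bagging", "BN", "IBK", "J48", "KStar", "SVM", "RF")
}

scale_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-9] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

scale_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")
}

# squared Euclidean cross-distance matrix (rows of A x rows of B)
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# 1-NN prediction; ties broken by the lower training index
nn1_from_dist <- function(D2, ytr) {
  idx <- max.col(-D2, ties.method = "first")
  as.numeric(ytr[idx] == "pos")
}

kstar_from_dist <- function(D2, ytr, blend = 0.2) {
  d <- sqrt(D2)
  d0 <- blend * mean(d)
  if (d0 < 1e-12) d0 <- 1e-12
  w <- exp(-d / d0)
  pos <- as.numeric(ytr == "pos")
  num <- w %*% pos
  den <- rowSums(w)
  den[den < 1e-300] <- 1e-300
  as.numeric(num / den)
}

bagging_from_dist <- function(D2, ytr, bags) {
  votes <- matrix(0, nrow(D2), length(bags))
  for (b in seq_along(bags)) {
    idx <- bags[[b]]
    votes[, b] <- nn1_from_dist(D2[, idx, drop = FALSE], ytr[idx])
  }
  rowMeans(votes)
}

make_bags <- function(n, n_bags, seed) {
  set.seed(seed)
  lapply(seq_len(n_bags), function(b) sample.int(n, n, replace = TRUE))
}

# Gaussian naive Bayes sufficient statistics
nb_stats <- function(X, y) {
  pos <- y == "pos"
  sd_floor <- 1e-6
  list(mu1 = colMeans(X[pos, , drop = FALSE]),
       mu0 = colMeans(X[!pos, , drop = FALSE]),
       s1 = pmax(apply(X[pos, , drop = FALSE], 2, stats::sd), sd_floor),
       s0 = pmax(apply(X[!pos, , drop = FALSE], 2, stats::sd), sd_floor),
       lp1 = log(mean(pos)), lp0 = log(mean(!pos)))
}

# per-feature log-likelihood difference contributions for test rows
nb_contrib <- function(st, X) {
  n <- nrow(X)
  ll1 <- matrix(0, n, ncol(X)); ll0 <- matrix(0, n, ncol(X))
  for (j in seq_len(ncol(X))) {
    ll1[, j] <- stats::dnorm(X[, j], st$mu1[j], st$s1[j], log = TRUE)
    ll0[, j] <- stats::dnorm(X[, j], st$mu0[j], st$s0[j], log = TRUE)
  }
  ll1 - ll0
}

nb_prob_from_contrib <- function(st, contrib_sum) {
  stats::plogis(st$lp1 - st$lp0 + contrib_sum)
}

#' Fit one roster classifier
#'
#' @param name roster name (see [classifier_roster]).
#' @param X numeric feature matrix (rows = instances).
#' @param y factor with levels `c("neg", "pos")`.
#' @param seed integer seed for the stochastic members.
#' @return fitted classifier object for [predict_classifier].
#' @export
fit_classifier <- function(name, X, y, seed = 1L) {
  name <- match.arg(name, classifier_roster())
  X <- as.matrix(X)
  y <- factor(y, levels = c("neg", "pos"))
  if (length(unique(y)) < 2L) stop("training labels are constant")
  st <- scale_train(X)
  obj <- switch(name,
    BN = nb_stats(st$X, y),
    IBK = list(Xtr = st$X, ytr = y),
    KStar = list(Xtr = st$X, ytr = y, blend = 0.2),
    Bagging = list(Xtr = st$X, ytr = y,
                   bags = make_bags(nrow(X), 10L, seed)),
    J48 = fit_j48(st$X, y),
    RF = ranger::ranger(
      x = st$X, y = y, num.trees = 100L, probability = TRUE,
      seed = seed, num.threads = 1L, verbose = FALSE),
    SVM = e1071::svm(x = st$X, y = y, kernel = "radial", cost = 1,
                     gamma = 1 / ncol(X), scale = FALSE),
    AdaBoostM1 = fit_adaboost(st$X, y, n_rounds = 50L, seed = seed))
  structure(list(name = name, obj = obj, scaling = st[c("center", "scale")],
                 features = colnames(X)),
            class = "mmrs_classifier")
}

fit_j48 <- function(Xs, y) {
  df <- as.data.frame(Xs)
  names(df) <- paste0("f", seq_len(ncol(Xs)))
  df$.y <- y
  rpart::rpart(.y ~ ., data = df, method = "class",
               parms = list(split = "information"),
               control = rpart::rpart.control(cp = 0.003, minsplit = 5L,
                                              xval = 0L, maxsurrogate = 0L))
}

# AdaBoost.M1 with a decision-stump base (the WEKA default base
# classifier).  The best weighted stump over all features and thresholds
# is found in O(n d) per round from presorted columns: with
# cw_i = cumsum(w * y) in sorted order and W_neg the total negative
# weight, the weighted error of "predict +1 above threshold i" is
# W_neg + cw_i, so the minimum/maximum of cw locate the best stump of
# either polarity.
fit_adaboost <- function(Xs, y, n_rounds = 50L, seed = 1L) {
  n <- nrow(Xs); d <- ncol(Xs)
  yn <- ifelse(y == "pos", 1, -1)
  ord <- lapply(seq_len(d), function(j) order(Xs[, j]))
  # valid split positions: between distinct adjacent sorted values
  valid <- lapply(seq_len(d), function(j) {
    xs <- Xs[ord[[j]], j]
    which(diff(xs) > 0)
  })
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    w_neg <- sum(w[yn < 0])
    best <- list(err = Inf)
    for (j in seq_len(d)) {
      v <- valid[[j]]
      if (!length(v)) next
      cw <- cumsum((w * yn)[ord[[j]]])
      errs_up <- w_neg + cw[v]          # predict +1 strictly above cut
      i_lo <- which.min(errs_up); i_hi <- which.max(errs_up)
      if (errs_up[i_lo] < best$err)
        best <- list(err = errs_up[i_lo], j = j, i = v[i_lo], pol = 1)
      if (1 - errs_up[i_hi] < best$err)
        best <- list(err = 1 - errs_up[i_hi], j = j, i = v[i_hi], pol = -1)
    }
    if (!is.finite(best$err) || best$err >= 0.5) break
    xs <- Xs[ord[[best$j]], best$j]
    thr <- unname((xs[best$i] + xs[best$i + 1]) / 2)
    pred <- best$pol * ifelse(Xs[, best$j] > thr, 1, -1)
    err <- max(best$err, 1e-12)
    alpha <- if (best$err < 1e-10) 10 else 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- c(j = best$j, thr = thr,
                                       pol = best$pol)
    alphas <- c(alphas, alpha)
    if (best$err < 1e-10) break       # perfect weak learner
    w <- w * exp(-alpha * yn * pred)
    w <- w / sum(w)
  }
  if (!length(stumps)) {              # no usable weak learner
    return(list(stumps = list(), alphas = 1,
                constant = mean(y == "pos")))
  }
  list(stumps = stumps, alphas = alphas)
}

#' Predict positive-class probabilities
#'
#' @param model object from [fit_classifier].
#' @param X feature matrix with the same columns as at fit time.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_classifier <- function(model, X) {
  if (!inherits(model, "mmrs_classifier")) stop("not a fitted classifier")
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X)))
    X <- X[, model$features, drop = FALSE]
  Xs <- scale_apply(X, model$scaling)
  obj <- model$obj
  switch(model$name,
    BN = {
      contrib <- nb_contrib(obj, Xs)
      nb_prob_from_contrib(obj, rowSums(contrib))
    },
    IBK = nn1_from_dist(cross_dist2(Xs, obj$Xtr), obj$ytr),
    KStar = kstar_from_dist(cross_dist2(Xs, obj$Xtr), obj$ytr, obj$blend),
    Bagging = bagging_from_dist(cross_dist2(Xs, obj$Xtr), obj$ytr, obj$bags),
    J48 = {
      df <- as.data.frame(Xs); names(df) <- paste0("f", seq_len(ncol(Xs)))
      predict(obj, df, type = "prob")[, "pos"]
    },
    RF = predict(obj, data = as.data.frame(Xs),
                 num.threads = 1L)$predictions[, "pos"],
    SVM = {
      dvm <- attr(predict(obj, Xs, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # e1071 orients decision values toward the first named class
      if (grepl("^neg", colnames(dvm)[1])) dv <- -dv
      stats::plogis(dv)
    },
    AdaBoostM1 = predict_adaboost(obj, Xs))
}

predict_adaboost <- function(obj, Xs) {
  if (!is.null(obj$constant)) return(rep(obj$constant, nrow(Xs)))
  score <- numeric(nrow(Xs))
  for (t in seq_along(obj$stumps)) {
    s <- obj$stumps[[t]]
    pred <- s[["pol"]] * ifelse(Xs[, s[["j"]]] > s[["thr"]], 1, -1)
    score <- score + obj$alphas[t] * pred
  }
  (score / sum(obj$alphas) + 1) / 2
}

# ---- cross-validation ------------------------------------------------------

#' Stratified fold assignment
#'
#' @param y factor of labels.
#' @param k requested folds; reduced (with a message) when the minority
#'   class has fewer than `k` members.
#' @param seed RNG seed.
#' @return integer fold id per instance, plus attribute `k`.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.factor(y)
  m <- min(table(y))
  if (m < 2L) stop("a class has fewer than 2 instances")
  if (m < k) {
    message("reducing folds from ", k, " to ", m,
            " (minority class size)")
    k <- m
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  attr(fold, "k") <- k
  fold
}

#' Out-of-fold cross-validated probabilities
#'
#' Every instance is predicted by a model that did not see it during
#' training.
#'
#' @param X feature matrix; `y` factor (`neg`/`pos`).
#' @param name roster classifier name.
#' @param folds fold count (default 10) or a precomputed fold vector.
#' @param seed seed controlling folds and classifier randomness.
#' @return numeric vector of out-of-fold positive-class probabilities.
#' @export
cv_predict <- function(X, y, name, folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("neg", "pos"))
  fold <- if (length(folds) == length(y)) folds
          else stratified_folds(y, folds, seed)
  k <- attr(fold, "k")
  if (is.null(k)) k <- max(fold)
  out <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- fold == f
    fit <- fit_classifier(name, X[!te, , drop = FALSE], y[!te],
                          seed = seed + f)
    out[te] <- predict_classifier(fit, X[te, , drop = FALSE])
  }
  out
}
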