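#' @title Optimal-model search
#'
#' @description Three-step search per reaction type: (1) rank features with
#' each selection method and drop zero scores; (2) backward elimination --
#' evaluate every roster classifier by stratified 10-fold CV at every
#' subset size m, m-1, ..., 1, eliminating the lowest-ranked feature each
#' step (the ranking is never recomputed); (3) among all grid cells with
#' CV AUC > 0.9 pick the highest CV ACC (ties: fewer features, then higher
#' AUC, then roster order).  A "none" arm evaluating the full feature set
#' competes alongside the four selection arms.  The enzyme indicator
#' columns are exempt from elimination: they carry the MMRS enzyme
#' identity (configurable via `exempt`).
#' @name model_search
NULL

#' Backward-elimination CV grid for one feature ranking
#'
#' Distance-based roster members (IBK, KStar, Bagging) and naive Bayes are
#' evaluated incrementally across subset sizes (the squared-distance /
#' log-likelihood contribution of an eliminated feature is subtracted),
#' tree/SVM members are refit per size.  Metrics are pooled over the
#' out-of-fold predictions.
#'
#' @param X numeric matrix (all candidate features, named columns).
#' @param y binary factor (`neg`/`pos`).
#' @param ranked_ids feature column indices ordered by descending score;
#'   elimination proceeds from the tail.
#' @param exempt_ids columns always retained (never eliminated, not counted
#'   in `size`).
#' @param classifiers roster subset (default all 8).
#' @param folds,seed CV control.
#' @return data.frame with one row per (classifier, size): `classifier`,
#'   `size`, `acc`, `auc`, `se`, `sp`, `bacc` (NaN where a fit failed).
#' @export
backward_eliminate <- function(X, y, ranked_ids, exempt_ids = integer(0),
                               classifiers = classifier_roster(),
                               folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("neg", "pos"))
  m <- length(ranked_ids)
  stopifnot(m >= 1L)
  fold <- stratified_folds(y, folds, seed)
  k <- attr(fold, "k")
  n <- nrow(X)
  ncls <- length(classifiers)
  prob <- array(NA_real_, dim = c(n, ncls, m),
                dimnames = list(NULL, classifiers, NULL))
  fast <- intersect(classifiers, c("BN", "IBK", "KStar", "Bagging"))
  slow <- setdiff(classifiers, fast)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    st <- scale_train(X[tr, , drop = FALSE])
    Xtr <- st$X
    Xte <- scale_apply(X[te, , drop = FALSE], st)
    ytr <- y[tr]
    # ---- incremental members ----
    if (length(fast)) {
      if ("BN" %in% fast) {
        nbst <- nb_stats(Xtr, ytr)
        contrib <- nb_contrib(nbst, Xte)
        ex_sum <- if (length(exempt_ids))
          rowSums(contrib[, exempt_ids, drop = FALSE]) else 0
        cs <- matrixcumsum(contrib[, ranked_ids, drop = FALSE])
        for (s in seq_len(m))
          prob[te, "BN", s] <- nb_prob_from_contrib(nbst, cs[, s] + ex_sum)
      }
      dist_members <- setdiff(fast, "BN")
      if (length(dist_members)) {
        cols <- c(ranked_ids, exempt_ids)
        D2 <- cross_dist2(Xte[, cols, drop = FALSE],
                          Xtr[, cols, drop = FALSE])
        if ("Bagging" %in% dist_members)
          bags <- make_bags(length(tr), 10L, seed + f)
        for (s in seq(m, 1L)) {
          if ("IBK" %in% dist_members)
            prob[te, "IBK", s] <- nn1_from_dist(D2, ytr)
          if ("KStar" %in% dist_members)
            prob[te, "KStar", s] <- kstar_from_dist(D2, ytr)
          if ("Bagging" %in% dist_members)
            prob[te, "Bagging", s] <- bagging_from_dist(D2, ytr, bags)
          if (s > 1L) {
            j <- ranked_ids[s]
            D2 <- D2 - outer(Xte[, j], Xtr[, j], "-")^2
            D2[D2 < 0] <- 0
          }
        }
      }
    }
    # ---- refit members ----
    for (s in seq_len(m)) {
      cols <- c(ranked_ids[seq_len(s)], exempt_ids)
      for (cl in slow) {
        p <- tryCatch(
          predict_classifier(
            fit_classifier(cl, X[tr, cols, drop = FALSE], ytr,
                           seed = seed + 1000L * f + s),
            X[te, cols, drop = FALSE]),
          error = function(e) rep(NaN, length(te)))
        prob[te, cl, s] <- p
      }
    }
  }
  grid <- do.call(rbind, lapply(seq_len(m), function(s) {
    do.call(rbind, lapply(classifiers, function(cl) {
      p <- prob[, cl, s]
      if (anyNA(p) || any(is.nan(p)))
        return(data.frame(classifier = cl, size = s, acc = NaN, auc = NaN,
                          se = NaN, sp = NaN, bacc = NaN))
      r <- report_row(y, p, 0.5)
      data.frame(classifier = cl, size = s, acc = r[["ACC"]],
                 auc = r[["AUC"]], se = r[["SE"]], sp = r[["SP"]],
                 bacc = r[["BACC"]])
    }))
  }))
  rownames(grid) <- NULL
  grid
}

matrixcumsum <- function(M) {
  if (ncol(M) == 1L) return(M)
  t(apply(M, 1, cumsum))
}

#' Run the full feature-selection-by-classifier search
#'
#' @param X numeric feature matrix (named columns).
#' @param y binary factor (`neg`/`pos`).
#' @param fs_methods selection arms (default all four).
#' @param classifiers roster subset (default all eight).
#' @param exempt labels never eliminated (default: enzyme indicators).
#' @param include_none evaluate the no-selection full-feature arm
#'   (default `TRUE`).
#' @param folds,seed CV control.
#' @return object of class `mmrs_search`: list with `grid` (data.frame
#'   fs/classifier/size/metrics), `subsets` (fs -> size -> column ids), and
#'   `score_tables`.
#' @export
run_model_search <- function(X, y, fs_methods = FS_METHODS,
                             classifiers = classifier_roster(),
                             exempt = ENZYMES, include_none = TRUE,
                             folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  exempt_ids <- which(colnames(X) %in% exempt)
  grids <- list(); subsets <- list(); tables <- list()
  for (fs in fs_methods) {
    tab <- score_features(X, y, fs, folds = folds, seed = seed)
    tables[[fs]] <- tab
    pruned <- tryCatch(prune_zero(tab, exempt = exempt),
                       error = function(e) NULL)
    if (is.null(pruned)) next
    ranked <- pruned[seq_len(attr(pruned, "n_ranked"))]
    g <- backward_eliminate(X, y, ranked, exempt_ids, classifiers,
                            folds = folds, seed = seed)
    g$fs <- fs
    grids[[fs]] <- g
    subsets[[fs]] <- lapply(seq_along(ranked), function(s)
      c(ranked[seq_len(s)], exempt_ids))
  }
  if (include_none) {
    nonex <- setdiff(seq_len(ncol(X)), exempt_ids)
    g <- backward_eliminate(X, y, ranked_ids = nonex,
                            exempt_ids = exempt_ids,
                            classifiers = classifiers,
                            folds = folds, seed = seed)
    # only the full-size row constitutes the "none" arm
    g <- g[g$size == length(nonex), , drop = FALSE]
    g$fs <- "none"
    grids[["none"]] <- g
    subsets[["none"]] <- stats::setNames(
      list(c(nonex, exempt_ids)), length(nonex))
  }
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL
  structure(list(grid = grid, subsets = subsets, score_tables = tables,
                 feature_names = colnames(X), exempt_ids = exempt_ids),
            class = "mmrs_search")
}

FS_ORDER <- c("chi", "ig", "gr", "relief", "none")

#' Select the optimal model from a completed search grid
#'
#' Among grid cells with CV AUC > `auc_gate` the cell with the highest CV
#' ACC wins; ties go to fewer features, then higher AUC, then roster
#' order, then selection-arm order.
#'
#' @param search an `mmrs_search` object.
#' @param auc_gate AUC threshold a candidate must exceed (default 0.9).
#' @return list describing the winning cell: `fs`, `classifier`, `size`,
#'   `feature_ids`, `feature_labels`, `acc`, `auc`, `se`, `sp`, `bacc`.
#' @export
select_optimal <- function(search, auc_gate = 0.9) {
  g <- search$grid
  g <- g[is.finite(g$auc) & g$auc > auc_gate, , drop = FALSE]
  if (!nrow(g))
    stop("no candidate model reaches AUC > ", auc_gate,
         "; review the data before modeling")
  ord <- order(-g$acc, g$size, -g$auc,
               match(g$classifier, classifier_roster()),
               match(g$fs, FS_ORDER))
  w <- g[ord[1L], ]
  ids <- search$subsets[[w$fs]][[as.character_size(w, search)]]
  list(fs = w$fs, classifier = w$classifier, size = w$size,
       feature_ids = ids,
       feature_labels = search$feature_names[ids],
       acc = w$acc, auc = w$auc, se = w$se, sp = w$sp, bacc = w$bacc)
}

as.character_size <- function(w, search) {
  if (w$fs == "none") 1L else w$size
}

#' Fit the final model of a search winner
#'
#' @param X,y full training data (same columns as the search).
#' @param selection result of [select_optimal].
#' @param reaction_type recorded in the manifest.
#' @param seed training seed.
#' @return an `mmrs_bundle`: `manifest` + fitted `model`.
#' @export
fit_final <- function(X, y, selection, reaction_type = NA_character_,
                      seed = 1L) {
  X <- as.matrix(X)
  cols <- selection$feature_ids
  model <- fit_classifier(selection$classifier, X[, cols, drop = FALSE],
                          y, seed = seed)
  non_enz <- setdiff(selection$feature_labels, ENZYMES)
  manifest <- list(
    reaction_type = reaction_type,
    classifier = selection$classifier,
    fs_method = selection$fs,
    n_features = selection$size,
    feature_ids = cols,
    feature_labels = selection$feature_labels,
    scheme = format_feature_scheme(match(non_enz, DESCRIPTOR_LABELS)),
    cv_acc = selection$acc, cv_auc = selection$auc,
    cv_se = selection$se, cv_sp = selection$sp, cv_bacc = selection$bacc,
    training_seed = seed,
    hyperparameters = roster_hyperparameters()[[selection$classifier]])
  structure(list(manifest = manifest, model = model),
            class = "mmrs_bundle")
}

roster_hyperparameters <- function() {
  list(
    AdaBoostM1 = "50 rounds, decision-stump base, early stop",
    Bagging = "10 bootstrap bags, 1-NN base",
    BN = "Gaussian naive Bayes, sd floor 1e-6",
    IBK = "k = 1, Euclidean, standardized features",
    J48 = "rpart entropy split, cp 0.003, minsplit 5",
    KStar = "exponential distance kernel, global blend 0.2",
    SVM = "RBF, C = 1, gamma = 1/d, logistic link on decision values",
    RF = "ranger, 100 trees, probability forest")
}

#' Parse / format a feature scheme string
#'
#' Scheme strings are comma-separated descriptor ids with hyphen or
#' en-dash ranges, e.g. `"1-10,13,25-33"`.
#'
#' @param scheme scheme string.
#' @return sorted integer vector of unique feature ids in 1..56.
#' @export
parse_feature_scheme <- function(scheme) {
  s <- gsub("–", "-", scheme)          # en-dash -> hyphen
  tokens <- trimws(strsplit(s, ",")[[1]])
  tokens <- tokens[nzchar(tokens)]
  ids <- unlist(lapply(tokens, function(tk) {
    if (grepl("-", tk)) {
      ab <- as.integer(strsplit(tk, "-")[[1]])
      if (length(ab) != 2L || anyNA(ab) || ab[1] > ab[2])
        stop("malformed range token: '", tk, "'")
      seq(ab[1], ab[2])
    } else {
      v <- as.integer(tk)
      if (is.na(v)) stop("malformed token: '", tk, "'")
      v
    }
  }))
  ids <- sort(unique(ids))
  if (any(ids < 1L | ids > 56L))
    stop("feature ids outside 1..56: ",
         paste(ids[ids < 1L | ids > 56L], collapse = ", "))
  ids
}

#' @rdname parse_feature_scheme
#' @param ids integer vector of feature ids.
#' @export
format_feature_scheme <- function(ids) {
  ids <- sort(unique(as.integer(ids)))
  if (!length(ids)) return("")
  runs <- split(ids, cumsum(c(1L, diff(ids) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r)
    else if (length(r) == 2L) paste(r, collapse = ",")
    else paste0(r[1], "-", r[length(r)])
  }, ""), collapse = ",")
}
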