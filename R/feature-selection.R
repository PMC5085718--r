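#' @title Feature scoring
#'
#' @description Four univariate scorers rank the 59 features (56 bond
#' descriptors + 3 enzyme indicators).  Continuous features are first
#' discretized by the Fayyad-Irani entropy/MDL method; features for which
#' MDL accepts no cut point fall into a single bin and score 0 under the
#' association scorers, which is what drives the "zero-scored features are
#' removed" pruning rule.  Scores are computed on the training part of each
#' of 10 stratified CV folds and averaged.
#'
#' * `chi` chi-squared statistic of the discretized feature against the
#'   class (no continuity correction);
#' * `ig` information gain H(class) - H(class | feature), in bits;
#' * `gr` gain ratio IG / H(feature);
#' * `relief` ReliefF with k = 10 nearest hits/misses over all instances,
#'   range-normalized differences.
#' @name feature_scoring
NULL

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Fayyad-Irani MDL discretization cut points
#'
#' Recursive binary splitting on class-entropy gain, accepting a split only
#' when the gain exceeds the MDL cost term.
#'
#' @param x numeric feature.
#' @param y class factor.
#' @return numeric vector of cut points (possibly empty).
#' @export
mdl_discretize <- function(x, y) {
  y <- as.integer(as.factor(y))
  o <- order(x)
  mdl_cuts(x[o], y[o])
}

mdl_cuts <- function(xs, ys) {
  n <- length(xs)
  if (n < 4L) return(numeric(0))
  # candidate cuts: midpoints between distinct adjacent values
  distinct <- which(diff(xs) > 0)
  if (!length(distinct)) return(numeric(0))
  k_tot <- length(unique(ys))
  if (k_tot < 2L) return(numeric(0))
  cnt_tot <- tabulate(ys, nbins = max(ys))
  ent_tot <- entropy_bits(cnt_tot)
  # cumulative class counts to evaluate all cuts in O(n * k)
  best_gain <- -Inf; best_i <- NA_integer_
  cum <- vapply(seq_len(max(ys)), function(l) cumsum(ys == l),
                numeric(n))
  for (i in distinct) {
    left <- cum[i, ]; right <- cnt_tot - left
    e1 <- entropy_bits(left); e2 <- entropy_bits(right)
    gain <- ent_tot - (i / n) * e1 - ((n - i) / n) * e2
    if (gain > best_gain) { best_gain <- gain; best_i <- i }
  }
  i <- best_i
  left <- cum[i, ]; right <- cnt_tot - left
  e1 <- entropy_bits(left); e2 <- entropy_bits(right)
  k1 <- sum(left > 0); k2 <- sum(right > 0)
  delta <- log2(3^k_tot - 2) - (k_tot * ent_tot - k1 * e1 - k2 * e2)
  threshold <- (log2(n - 1) + delta) / n
  if (best_gain <= threshold) return(numeric(0))
  cut <- (xs[i] + xs[i + 1]) / 2
  c(mdl_cuts(xs[seq_len(i)], ys[seq_len(i)]), cut,
    mdl_cuts(xs[(i + 1):n], ys[(i + 1):n]))
}

discretize_apply <- function(x, cuts) {
  if (!length(cuts)) return(rep(1L, length(x)))
  findInterval(x, sort(cuts)) + 1L
}

chi_score_binned <- function(xd, y) {
  tab <- table(xd, y)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

ig_score_binned <- function(xd, y) {
  tab <- table(xd, y)
  n <- sum(tab)
  hy <- entropy_bits(colSums(tab))
  hyx <- sum(vapply(seq_len(nrow(tab)), function(i)
    sum(tab[i, ]) / n * entropy_bits(tab[i, ]), 0))
  hy - hyx
}

gr_score_binned <- function(xd, y) {
  ig <- ig_score_binned(xd, y)
  hx <- entropy_bits(table(xd))
  if (hx < 1e-12) return(0)
  ig / hx
}

#' ReliefF feature weights
#'
#' @param X numeric matrix; `y` binary factor.
#' @param k neighbors per class (default 10).
#' @return numeric weight per feature (may be negative).
#' @export
relieff <- function(X, y, k = 10L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng < 1e-12] <- 1
  Xn <- sweep(X, 2, rng, "/")
  W <- numeric(p)
  # distance matrix in blocks to bound memory
  blk <- max(1L, floor(2e7 / n))
  x2 <- rowSums(Xn^2)
  for (start in seq(1L, n, by = blk)) {
    rows <- start:min(start + blk - 1L, n)
    D2 <- outer(x2[rows], x2, "+") - 2 * tcrossprod(Xn[rows, , drop = FALSE], Xn)
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      d <- D2[ri, ]; d[i] <- Inf
      same <- y == y[i]
      hits <- which(same); hits <- hits[hits != i]
      miss <- which(!same)
      kh <- min(k, length(hits)); km <- min(k, length(miss))
      if (kh == 0L || km == 0L) next
      nh <- hits[order(d[hits])[seq_len(kh)]]
      nm <- miss[order(d[miss])[seq_len(km)]]
      dh <- abs(sweep(Xn[nh, , drop = FALSE], 2, Xn[i, ]))
      dm <- abs(sweep(Xn[nm, , drop = FALSE], 2, Xn[i, ]))
      W <- W - colSums(dh) / (n * kh) + colSums(dm) / (n * km)
    }
  }
  W
}

FS_METHODS <- c("chi", "ig", "gr", "relief")

#' Score all features with one selection method
#'
#' Scores are computed on the training part of each stratified CV fold and
#' averaged over folds.
#'
#' @param X numeric feature matrix with column names.
#' @param y binary factor (`neg`/`pos`).
#' @param method one of `"chi"`, `"ig"`, `"gr"`, `"relief"`.
#' @param folds CV folds (default 10).
#' @param seed RNG seed.
#' @return data.frame: `id`, `label`, `score` (fold mean), `rank`
#'   (1 = best; ties broken by lower id).
#' @export
score_features <- function(X, y, method = FS_METHODS, folds = 10L,
                           seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- factor(y, levels = c("neg", "pos"))
  if (length(unique(y)) < 2L) stop("class label is constant")
  fold <- stratified_folds(y, folds, seed)
  k <- attr(fold, "k")
  acc <- matrix(0, ncol(X), k)
  for (f in seq_len(k)) {
    tr <- fold != f
    acc[, f] <- score_features_once(X[tr, , drop = FALSE], y[tr], method)
  }
  score <- rowMeans(acc)
  data.frame(id = seq_len(ncol(X)),
             label = colnames(X),
             score = score,
             rank = rank(-score, ties.method = "first"),
             stringsAsFactors = FALSE)
}

score_features_once <- function(X, y, method) {
  if (method == "relief") return(relieff(X, y, k = 10L))
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    xd <- discretize_apply(x, mdl_discretize(x, y))
    switch(method,
           chi = chi_score_binned(xd, y),
           ig = ig_score_binned(xd, y),
           gr = gr_score_binned(xd, y))
  }, 0)
}

#' Remove zero-scored features
#'
#' Features scoring 0 (or below, for Relief weights) are removed; the rest
#' are returned in descending score order.  Features named in `exempt` are
#' never removed and are appended after the ranked subset.
#'
#' @param table result of [score_features].
#' @param exempt character vector of labels to always retain (default: the
#'   enzyme indicator columns).
#' @return integer vector of feature ids (attribute `labels` carries the
#'   names); errors when every non-exempt score is zero.
#' @export
prune_zero <- function(table, exempt = ENZYMES) {
  main <- table[!(table$label %in% exempt), , drop = FALSE]
  keep <- main[main$score > 0, , drop = FALSE]
  if (!nrow(keep)) stop("all feature scores are zero")
  keep <- keep[order(-keep$score, keep$id), , drop = FALSE]
  ids <- keep$id
  ex <- table$id[table$label %in% exempt]
  out <- c(ids, ex)
  attr(out, "labels") <- table$label[out]
  attr(out, "n_ranked") <- length(ids)
  out
}
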