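# Independent brute-force oracles used to validate the fast implementations.

# All automorphisms of the heavy-atom graph by plain backtracking.
# Vertex invariant: element, formal charge, hydrogen count, aromatic flag.
# Edge invariant: bond kind (order, aromatic = 1.5).  Hydrogens are
# interchangeable leaves, so heavy-graph automorphisms induce all bond
# equivalences.
brute_automorphisms <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  nh <- length(heavy)
  pos <- match(seq_len(nrow(mol$atoms)), heavy)   # atom -> heavy position
  inv <- vapply(heavy, function(i) {
    hs <- sum(mol$atoms$element[mol$adj[[i]]] == "H")
    paste(mol$atoms$element[i], mol$atoms$charge[i], hs,
          mol$atoms$aromatic[i])
  }, "")
  kind <- matrix(0, nh, nh)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- pos[mol$bonds$a[k]]; b <- pos[mol$bonds$b[k]]
    if (is.na(a) || is.na(b)) next
    v <- if (mol$bonds$aromatic[k]) 1.5 else mol$bonds$order[k]
    kind[a, b] <- v; kind[b, a] <- v
  }
  perms <- list()
  map <- integer(nh)
  recurse <- function(d) {
    if (d > nh) {
      perms[[length(perms) + 1L]] <<- map
      return(invisible())
    }
    for (img in seq_len(nh)) {
      if (img %in% map[seq_len(d - 1L)]) next
      if (inv[img] != inv[d]) next
      ok <- TRUE
      for (prev in seq_len(d - 1L)) {
        if (kind[d, prev] != kind[img, map[prev]]) { ok <- FALSE; break }
      }
      if (ok) {
        map[d] <<- img
        recurse(d + 1L)
        map[d] <<- 0L
      }
    }
  }
  recurse(1L)
  list(perms = perms, heavy = heavy)
}

# Partition candidate (a, b) pairs into equivalence classes under the
# brute-force automorphism group.  For C-H pairs only the heavy atom has
# to map (hydrogens on one carbon are equivalent leaves).
brute_pair_classes <- function(mol, pairs) {
  au <- brute_automorphisms(mol)
  hp <- match(seq_len(nrow(mol$atoms)), au$heavy)
  n <- nrow(pairs)
  cls <- seq_len(n)
  equivalent <- function(i, j) {
    ai <- hp[pairs$a[i]]; aj <- hp[pairs$a[j]]
    b_is_h <- mol$atoms$element[pairs$b[i]] == "H"
    bi <- if (b_is_h) NA else hp[pairs$b[i]]
    bj <- if (b_is_h) NA else hp[pairs$b[j]]
    for (p in au$perms) {
      if (p[ai] != aj) next
      if (b_is_h || p[bi] == bj) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (cls[j] != j) next
      if (equivalent(i, j)) cls[j] <- cls[i]
    }
  }
  match(cls, unique(cls))
}

# canonical form of a partition for comparing two class assignments
partition_signature <- function(cls) {
  unname(split(seq_along(cls), cls))[order(vapply(
    unname(split(seq_along(cls), cls)), min, 0L))]
}

# trapezoidal ROC integration, the slow independent AUC oracle
trapezoid_auc <- function(labels, scores) {
  y <- as.logical(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[y] >= t), 0), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!y] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
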