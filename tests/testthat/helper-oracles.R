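# Independent brute-force oracles used to check the package's
# implementations. These deliberately reuse none of the package's code
# paths: direct textbook formulas, exhaustive enumeration, and naive
# scans.

# textbook pooled two-sample t statistic
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# hypergeometric upper tail P(X >= k) by enumerating every size-n subset
oracle_hyper_enum <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  overlaps <- colSums(sets <= K)  # class genes are 1..K
  mean(overlaps >= k)
}

# all maximal same-cluster member sets within a window, by enumerating
# every window placement and splitting window members into max_gap
# chains, then removing duplicates and subsets
oracle_windowed_sets <- function(r, window = 9L, min_members = 3L,
                                 max_gap = 5L) {
  r <- sort(r)
  if (length(r) == 0L) return(list())
  sets <- list()
  for (a in min(r):max(r)) {
    w <- r[r >= a & r <= a + window - 1L]
    if (length(w) < min_members) next
    breaks <- c(0L, which(diff(w) > max_gap), length(w))
    for (i in seq_len(length(breaks) - 1L)) {
      ch <- w[(breaks[i] + 1L):breaks[i + 1L]]
      if (length(ch) >= min_members)
        sets[[length(sets) + 1L]] <- ch
    }
  }
  sets <- unique(sets)
  if (length(sets) < 2L) return(sets)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j || !keep[i]) next
      if (length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) keep[i] <- FALSE
    }
  }
  sets[keep]
}

# maximal runs of identical labels, naive element-by-element scan
oracle_patches <- function(labels, min_run = 3L) {
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && !is.na(labels[j + 1L]) && !is.na(labels[i]) &&
             labels[j + 1L] == labels[i]) j <- j + 1L
    if (!is.na(labels[i]) && j - i + 1L >= min_run)
      out[[length(out) + 1L]] <- list(cluster = labels[i],
                                      ranks = (i:j) - 1L)
    i <- j + 1L
  }
  out
}

# canonical string form of a list of rank sets, for set comparison
canon_sets <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","),
              character(1)))
}

# one extra fuzzy c-means update round, written independently with
# explicit loops over the stationarity equations
oracle_fcm_step <- function(x, v, m) {
  n <- nrow(x); cc <- nrow(v)
  d2 <- matrix(0, n, cc)
  for (i in seq_len(n)) for (j in seq_len(cc))
    d2[i, j] <- sum((x[i, ] - v[j, ])^2)
  u <- matrix(0, n, cc)
  for (i in seq_len(n)) {
    if (any(d2[i, ] == 0)) {
      u[i, which(d2[i, ] == 0)[1]] <- 1
    } else {
      for (j in seq_len(cc))
        u[i, j] <- 1 / sum((d2[i, j] / d2[i, ])^(1 / (m - 1)))
    }
  }
  v_new <- matrix(0, cc, ncol(x))
  for (j in seq_len(cc)) {
    w <- u[, j]^m
    v_new[j, ] <- colSums(x * w) / sum(w)
  }
  list(u = u, v = v_new)
}
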