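# Fuzzy c-means clustering of standardized induction profiles, and
# identification of the clusters that carry the characterized
# cellulase/hemicellulase (reference) genes.

#' Standardize per-gene profiles
#'
#' Row-wise z-scoring (mean 0, sample sd 1) of a gene x condition profile
#' matrix, the conventional preprocessing before fuzzy c-means so that
#' clustering reflects profile shape rather than amplitude. Rows with
#' zero variance (or any missing value) carry no shape information and
#' are dropped.
#'
#' @param profiles numeric matrix with >= 2 columns, gene ids as rownames
#' @return list of class `"standardized_profiles"`: `matrix` (retained,
#'   standardized rows) and `dropped_genes`
#' @export
standardize_profiles <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  if (is.null(rownames(profiles))) stop("profiles need gene rownames")
  mu <- rowMeans(profiles)
  sd_ <- apply(profiles, 1L, stats::sd)
  keep <- is.finite(sd_) & sd_ > 0 & !apply(profiles, 1L, anyNA)
  z <- (profiles[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  structure(list(matrix = z,
                 dropped_genes = rownames(profiles)[!keep]),
            class = "standardized_profiles")
}

#' Fuzzy c-means clustering
#'
#' Minimizes the fuzzy within-cluster sum of squares
#' `J_m = sum_i sum_j u_ij^m ||x_i - v_j||^2` by the standard alternating
#' updates: memberships
#' `u_ij = 1 / sum_k (||x_i - v_j|| / ||x_i - v_k||)^(2/(m-1))` and
#' centroids `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`. A point coinciding
#' exactly with a centroid receives full membership in (the first of)
#' the coincident centroids. Each restart seeds the centroids with `c`
#' distinct genes drawn under the run seed; the restart with the lowest
#' final objective is kept.
#'
#' @param profiles a [standardize_profiles()] result or a plain numeric
#'   matrix
#' @param c number of clusters (>= 2, < number of genes)
#' @param m fuzzifier (> 1); `m -> 1` approaches hard k-means
#' @param tol convergence tolerance on `max |delta U|`
#' @param max_iter iteration cap per restart
#' @param seed integer seed controlling initialization
#' @param n_restarts independent restarts, best objective kept
#' @return list of class `"fcm_model"`: `centroids` (c x p), `membership`
#'   (gene x c, rows summing to 1), `c`, `m`, `objective_trace`
#'   (non-increasing), `iterations`, `converged`, `seed`
#' @export
fuzzy_cmeans <- function(profiles, c, m = 1.25, tol = 1e-6, max_iter = 200L,
                         seed = 1L, n_restarts = 3L) {
  x <- if (inherits(profiles, "standardized_profiles")) profiles$matrix
       else profiles
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in profiles")
  n <- nrow(x)
  if (c < 2L) stop("c must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (c >= n) stop("c must be smaller than the number of genes")

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1L, fcm_single(x, c, m, tol, max_iter))
    if (is.null(best) ||
        fit$objective_trace[length(fit$objective_trace)] <
          best$objective_trace[length(best$objective_trace)])
      best <- fit
  }
  best$seed <- seed
  best$c <- c
  best$m <- m
  class(best) <- "fcm_model"
  best
}

# squared Euclidean distances gene x centroid
fcm_dist2 <- function(x, v) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(v)) +
    matrix(rowSums(v^2), nrow(x), nrow(v), byrow = TRUE) -
    2 * x %*% t(v)
  pmax(d2, 0)
}

fcm_memberships <- function(d2, m) {
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  zero <- d2 <= .Machine$double.eps
  hit <- which(rowSums(zero) > 0L)
  for (i in hit) {
    u[i, ] <- 0
    u[i, which(zero[i, ])[1L]] <- 1
  }
  u
}

fcm_single <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  v <- x[sample.int(n, c), , drop = FALSE]
  d2 <- fcm_dist2(x, v)
  u <- fcm_memberships(d2, m)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    w <- colSums(um)
    # a starved cluster keeps its previous centroid
    v_new <- v
    pos <- w > .Machine$double.eps
    v_new[pos, ] <- (t(um[, pos, drop = FALSE]) %*% x) / w[pos]
    v <- v_new
    d2 <- fcm_dist2(x, v)
    u_new <- fcm_memberships(d2, m)
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  dimnames(u) <- list(rownames(x), paste0("cluster", seq_len(c)))
  dimnames(v) <- list(paste0("cluster", seq_len(c)), colnames(x))
  list(centroids = v, membership = u, objective_trace = trace,
       iterations = iter, converged = converged)
}

#' Harden fuzzy memberships
#'
#' Assigns each gene to its maximum-membership cluster (ties broken by
#' the lowest cluster index) and flags core members whose maximum
#' membership reaches `alpha`.
#'
#' @param model an `fcm_model`
#' @param alpha core-membership threshold in (0, 1], default 0.5
#' @return data.frame of class `"cluster_assignment"`: `gene_id`,
#'   `cluster` (integer), `membership` (the maximum), `core`
#' @export
assign_clusters <- function(model, alpha = 0.5) {
  stopifnot(inherits(model, "fcm_model"))
  u <- model$membership
  hard <- apply(u, 1L, which.max)  # which.max takes the first (lowest) tie
  mx <- u[cbind(seq_len(nrow(u)), hard)]
  out <- data.frame(gene_id = rownames(u), cluster = as.integer(hard),
                    membership = as.numeric(mx), core = mx >= alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Clusters carrying the reference genes, and their co-clustered genes
#'
#' Ranks clusters by how many characterized cellulase/hemicellulase
#' (reference) genes they hold and flags the smallest set of top clusters
#' covering at least `min_fraction` of the references (the screen's
#' analogue of "the majority of the characterized genes fell in two
#' clusters"). All non-reference genes sharing the flagged clusters are
#' returned as co-clustered.
#'
#' @param assignment a [assign_clusters()] result
#' @param reference_gene_ids non-empty character vector of reference ids
#'   present in the assignment
#' @param min_fraction cumulative fraction of references the flagged
#'   clusters must cover, default 0.9
#' @param core_only restrict co-clustered genes to core members
#' @return list: `clusters` (flagged cluster ids), `co_clustered`
#'   (character vector), `counts` (data.frame cluster/n_reference)
#' @export
reference_clusters <- function(assignment, reference_gene_ids,
                               min_fraction = 0.9, core_only = FALSE) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (length(reference_gene_ids) == 0L)
    stop("reference gene set is empty")
  miss <- setdiff(reference_gene_ids, assignment$gene_id)
  if (length(miss))
    stop("references absent from assignment: ", paste(miss, collapse = ", "))
  ref <- assignment[assignment$gene_id %in% reference_gene_ids, ]
  cnt <- table(factor(ref$cluster))
  ord <- order(-as.integer(cnt), as.integer(names(cnt)))
  cnt <- cnt[ord]
  cum <- cumsum(as.integer(cnt)) / length(reference_gene_ids)
  n_flag <- which(cum >= min_fraction)[1L]
  flagged <- as.integer(names(cnt)[seq_len(n_flag)])
  sel <- assignment$cluster %in% flagged &
    !(assignment$gene_id %in% reference_gene_ids)
  if (core_only) sel <- sel & assignment$core
  list(clusters = flagged,
       co_clustered = assignment$gene_id[sel],
       counts = data.frame(cluster = as.integer(names(cnt)),
                           n_reference = as.integer(cnt)))
}
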