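test_that("row standardization is exact z-scoring and drops flat rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 6))
  z <- standardize_profiles(m)
  expect_equal(unname(z$matrix["a", ]), c(-1, 0, 1))
  expect_equal(z$dropped_genes, "b")
  set.seed(1)
  r <- matrix(rnorm(600), 100, 6,
              dimnames = list(sprintf("g%d", 1:100), NULL))
  zr <- standardize_profiles(r)$matrix
  expect_true(all(abs(rowMeans(zr)) < 1e-9))
  expect_true(all(abs(apply(zr, 1, sd) - 1) < 1e-9))
})

test_that("well-separated groups get near-hard memberships", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60, mean = 5, sd = 0.05), 30, 2),
             matrix(rnorm(60, mean = -5, sd = 0.05), 30, 2))
  rownames(x) <- sprintf("g%d", 1:60)
  fit <- fuzzy_cmeans(x, c = 2, m = 1.25, seed = 4)
  expect_true(all(apply(fit$membership, 1, max) > 0.99))
  got <- fit$centroids[order(fit$centroids[, 1]), ]
  want <- rbind(colMeans(x[31:60, ]), colMeans(x[1:30, ]))
  expect_equal(unname(got), unname(want), tolerance = 1e-3)
})

test_that("an equidistant point splits its membership evenly", {
  x <- rbind(matrix(rep(c(-1, 0), each = 20), 20, 2),
             matrix(rep(c(1, 0), each = 20), 20, 2),
             c(0, 0))
  rownames(x) <- sprintf("g%d", 1:41)
  fit <- fuzzy_cmeans(x, c = 2, m = 1.5, seed = 1, n_restarts = 5)
  expect_equal(unname(fit$membership[41, ]), c(0.5, 0.5), tolerance = 1e-6)
  # group points sit near (not on) their centroid, which the midpoint
  # pulls slightly inward, so their membership is almost but not all one
  expect_true(all(apply(fit$membership[1:40, ], 1, max) > 0.999))
})

test_that("converged solutions satisfy the stationarity equations", {
  set.seed(3)
  x <- matrix(rnorm(160), 40, 4, dimnames = list(sprintf("g%d", 1:40), NULL))
  fit <- fuzzy_cmeans(x, c = 3, m = 1.6, tol = 1e-9, max_iter = 500,
                      seed = 6)
  step <- oracle_fcm_step(x, fit$centroids, m = 1.6)
  expect_lt(max(abs(step$u - fit$membership)), 1e-6)
  step2 <- oracle_fcm_step(x, step$v, m = 1.6)
  expect_lt(max(abs(step$v - fit$centroids)), 1e-6)
  expect_lt(max(abs(step2$v - step$v)), 1e-6)
})

test_that("memberships are a proper partition and J is non-increasing", {
  set.seed(4)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(sprintf("g%d", 1:60), NULL))
  for (s in 1:5) {
    fit <- fuzzy_cmeans(x, c = 4, m = 1.25, seed = s, n_restarts = 1)
    expect_true(all(fit$membership >= 0 & fit$membership <= 1))
    expect_equal(unname(rowSums(fit$membership)), rep(1, 60),
                 tolerance = 1e-9)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(1, tr[-length(tr)])))
  }
})

test_that("gene order does not change the recovered partition", {
  set.seed(5)
  x <- rbind(matrix(rnorm(80, 3, 0.3), 20, 4),
             matrix(rnorm(80, -3, 0.3), 20, 4),
             matrix(rnorm(80, 0, 0.3), 20, 4))
  rownames(x) <- sprintf("g%02d", 1:60)
  f1 <- assign_clusters(fuzzy_cmeans(x, c = 3, seed = 2))
  perm <- sample(60)
  f2 <- assign_clusters(fuzzy_cmeans(x[perm, ], c = 3, seed = 2))
  l1 <- f1$cluster[match(rownames(x), f1$gene_id)]
  l2 <- f2$cluster[match(rownames(x), f2$gene_id)]
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})

test_that("our optimum agrees with an independent fuzzy c-means fit", {
  set.seed(6)
  x <- rbind(matrix(rnorm(100, 4, 0.4), 25, 4),
             matrix(rnorm(100, -4, 0.4), 25, 4),
             matrix(rnorm(100, 0, 0.4), 25, 4))
  rownames(x) <- sprintf("g%02d", 1:75)
  ours <- assign_clusters(fuzzy_cmeans(x, c = 3, m = 1.5, seed = 3))
  theirs <- e1071::cmeans(x, centers = 3, m = 1.5)
  expect_equal(mclust::adjustedRandIndex(ours$cluster,
                                         theirs$cluster[ours$gene_id]), 1)
})

test_that("hardening follows argmax with documented tie-breaks", {
  u <- rbind(c(0.7, 0.2, 0.1), c(0.34, 0.33, 0.33), c(0.5, 0.5, 0))
  rownames(u) <- c("a", "b", "c")
  model <- structure(list(membership = u), class = "fcm_model")
  a <- assign_clusters(model, alpha = 0.5)
  expect_equal(a$cluster, c(1L, 1L, 1L))
  expect_equal(a$core, c(TRUE, FALSE, TRUE))
})

test_that("reference clusters are flagged by cumulative coverage", {
  assignment <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    cluster = rep(c(1L, 2L, 3L, 4L), each = 10),
    membership = 0.9, core = TRUE, stringsAsFactors = FALSE)
  class(assignment) <- c("cluster_assignment", "data.frame")
  refs <- c(sprintf("g%02d", 1:8),    # 8 in cluster 1
            sprintf("g%02d", 11:15),  # 5 in cluster 2
            "g21")                    # 1 in cluster 3
  rc <- reference_clusters(assignment, refs, min_fraction = 0.9)
  expect_equal(rc$clusters, c(1L, 2L))
  expect_setequal(rc$co_clustered,
                  setdiff(sprintf("g%02d", 1:20), refs))
  one <- reference_clusters(assignment, sprintf("g%02d", 31:33))
  expect_equal(one$clusters, 4L)
  expect_error(reference_clusters(assignment, character(0)), "empty")
})

test_that("degenerate clustering inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  expect_error(fuzzy_cmeans(x, c = 10), "smaller")
  expect_error(fuzzy_cmeans(x, c = 2, m = 1), "m must be > 1")
  x[1, 1] <- NA
  expect_error(fuzzy_cmeans(x, c = 2), "non-finite")
})
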