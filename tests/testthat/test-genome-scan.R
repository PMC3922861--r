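assignment_for <- function(loci, clusters) {
  data.frame(gene_id = loci$gene_id,
             cluster = rep_len(clusters, nrow(loci)),
             stringsAsFactors = FALSE)
}

test_that("genes are ranked by start position within each scaffold", {
  loci <- data.frame(gene_id = c("a", "b", "c"), scaffold = "s1",
                     start = c(100, 900, 500), end = c(150, 950, 550),
                     strand = "+", stringsAsFactors = FALSE)
  ord <- order_genes(loci)
  expect_equal(ord$rank[match(c("a", "b", "c"), ord$gene_id)],
               c(0L, 2L, 1L))
  two <- rbind(loci, data.frame(gene_id = c("d", "e"), scaffold = "s2",
                                start = c(10, 5), end = c(20, 8),
                                strand = "-"))
  ord2 <- order_genes(two)
  expect_equal(ord2$rank[ord2$scaffold == "s2"], c(0L, 1L))
  expect_equal(ord2$rank[ord2$scaffold == "s1"], c(0L, 1L, 2L))
  expect_error(order_genes(rbind(loci, loci[1, ])), "duplicate")
  bad <- loci; bad$end[1] <- 50
  expect_error(order_genes(bad), "inverted")
})

test_that("a saturated window is one region; sparse members are none", {
  set.seed(1)
  loci <- order_genes(random_loci(9))
  regions <- find_coregulated_regions(loci, assignment_for(loci, 1L))
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$n_members, 9L)
  expect_equal(c(regions$first_rank, regions$last_rank), c(0L, 8L))

  # members at ranks 0, 5, 10: no window of nine holds three of them
  loci2 <- order_genes(random_loci(11))
  cl <- ifelse(loci2$rank %in% c(0L, 5L, 10L), 1L, 2L)
  sparse <- find_coregulated_regions(
    loci2, data.frame(gene_id = loci2$gene_id, cluster = cl),
    exclude_clusters = 2L)
  expect_equal(nrow(sparse), 0L)
  expect_error(find_coregulated_regions(loci2, assignment_for(loci2, 1L),
                                        window = 2, min_members = 3),
               "at least")
})

test_that("adjacent patches follow the run-length rule", {
  set.seed(2)
  loci <- order_genes(random_loci(4, shuffle = FALSE))
  p1 <- find_adjacent_patches(loci, assignment_for(loci, c(1, 1, 1, 2)))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$cluster, 1L)
  expect_equal(c(p1$first_rank, p1$last_rank), c(0L, 2L))

  loci5 <- order_genes(random_loci(5, shuffle = FALSE))
  p2 <- find_adjacent_patches(loci5,
                              assignment_for(loci5, c(1, 1, 2, 1, 1)))
  expect_equal(nrow(p2), 0L)
})

test_that("windowed and adjacency scans match brute-force enumeration", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    k <- sample(1:6, 1)
    loci <- order_genes(random_loci(n, scaffold = sprintf("s%d", rep)))
    assignment <- data.frame(gene_id = loci$gene_id,
                             cluster = sample.int(k, n, replace = TRUE))
    regions <- find_coregulated_regions(loci, assignment)
    patches <- find_adjacent_patches(loci, assignment)
    cl_of <- assignment$cluster[match(loci$gene_id, assignment$gene_id)]
    labels_in_rank_order <- cl_of[order(loci$rank)]
    got_w <- character(0); want_w <- character(0)
    for (cc in sort(unique(assignment$cluster))) {
      r <- sort(loci$rank[cl_of == cc])
      want <- oracle_windowed_sets(r)
      if (length(want))
        want_w <- c(want_w, paste0("c", cc, ":", canon_sets(want)))
    }
    if (nrow(regions)) {
      rank_of <- setNames(loci$rank, loci$gene_id)
      got_w <- vapply(seq_len(nrow(regions)), function(i) {
        g <- strsplit(regions$gene_ids[i], ",")[[1]]
        paste0("c", regions$cluster[i], ":",
               paste(sort(rank_of[g]), collapse = ","))
      }, character(1))
    }
    expect_setequal(got_w, want_w)

    want_p <- oracle_patches(labels_in_rank_order)
    expect_equal(nrow(patches), length(want_p))
    if (length(want_p)) {
      want_keys <- sort(vapply(want_p, function(p)
        paste0("c", p$cluster, ":", min(p$ranks), "-", max(p$ranks)),
        character(1)))
      got_keys <- sort(sprintf("c%d:%d-%d", patches$cluster,
                               patches$first_rank, patches$last_rank))
      expect_equal(got_keys, want_keys)
    }
  }
})

test_that("coordinate shifts change bp spans but not memberships", {
  set.seed(3)
  loci <- random_loci(30)
  a <- assignment_for(order_genes(loci), rep(c(1, 2), 15))
  r1 <- find_coregulated_regions(order_genes(loci), a)
  shifted <- loci
  shifted$start <- shifted$start + 10000L
  shifted$end <- shifted$end + 10000L
  r2 <- find_coregulated_regions(order_genes(shifted), a)
  expect_equal(r1$gene_ids, r2$gene_ids)
  expect_equal(r1$first_rank, r2$first_rank)
  expect_equal(r2$start_bp, r1$start_bp + 10000L)
})

test_that("every long-enough patch is contained in a windowed region", {
  set.seed(4)
  for (rep in 1:30) {
    n <- sample(10:50, 1)
    loci <- order_genes(random_loci(n, scaffold = sprintf("p%d", rep)))
    assignment <- data.frame(gene_id = loci$gene_id,
                             cluster = sample.int(3, n, replace = TRUE))
    patches <- find_adjacent_patches(loci, assignment)
    regions <- find_coregulated_regions(loci, assignment)
    if (nrow(patches) == 0) next
    region_sets <- strsplit(regions$gene_ids, ",")
    for (i in seq_len(nrow(patches))) {
      pg <- strsplit(patches$gene_ids[i], ",")[[1]]
      expect_true(any(vapply(region_sets, function(s) all(pg %in% s),
                             logical(1))))
    }
  }
})

test_that("neighbor annotation reports roles, distances and region flags", {
  loci <- order_genes(random_loci(8, shuffle = FALSE))
  ids <- loci$gene_id[order(loci$rank)]
  roles <- setNames(rep("other", 8), ids)
  roles[ids[6]] <- "regulator"
  roles[ids[7]] <- "CAZy"
  assignment <- data.frame(gene_id = ids, cluster = c(1, 1, 1, 2, 2, 1, 1, 1))
  regions <- find_adjacent_patches(loci, assignment)
  nb <- annotate_neighbors(loci, regions, ids[6], roles)
  expect_true(all(c(ids[5], ids[7]) %in% nb$neighbors$neighbor))
  expect_equal(nb$neighbors$distance, c(1L, 1L))
  expect_true(nb$candidates$near_cazy_or_transporter)
  expect_true(nb$candidates$in_region)

  lone <- data.frame(gene_id = "solo", scaffold = "sX", start = 1,
                     end = 10, strand = "+", stringsAsFactors = FALSE)
  nb2 <- annotate_neighbors(order_genes(lone), regions[0, ], "solo",
                            c(solo = "regulator"))
  expect_equal(nrow(nb2$neighbors), 0L)
  expect_false(nb2$candidates$near_cazy_or_transporter)
})
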