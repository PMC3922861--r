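test_that("zero-noise datasets reproduce planted effects exactly", {
  cfg <- sim_config(n_genes = 60, n_scaffolds = 2, n_clusters = 1,
                    cluster_sizes = 20L,
                    effect_log2 = matrix(2, 1, 4),
                    time_profiles = "step", noise_sd = 0,
                    n_regions = 1, region_span = 4, n_regulators = 2,
                    n_reference = 1, rng_seed = 3)
  ds <- simulate_experiment(cfg)
  des <- ds$expression$design
  members <- names(ds$truth$cluster)[ds$truth$cluster == 1]
  for (s in cfg$substrates) {
    ind <- des$sample_id[des$role == "induced" & des$substrate == s &
                           des$time_h == 6]
    ctl <- des$sample_id[des$role == "control" & des$time_h == 6]
    diff <- rowMeans(ds$expression$matrix[members, ind]) -
      rowMeans(ds$expression$matrix[members, ctl])
    expect_equal(unname(diff), rep(2, length(members)))
  }
  # control samples and background genes carry no effect
  bg <- names(ds$truth$cluster)[ds$truth$cluster == 0]
  ind <- des$sample_id[des$role == "induced" & des$time_h == 17]
  ctl <- des$sample_id[des$role == "control" & des$time_h == 17]
  expect_equal(unname(rowMeans(ds$expression$matrix[bg, ind]) -
                        rowMeans(ds$expression$matrix[bg, ctl])),
               rep(0, length(bg)))
})

test_that("identical config and seed give bitwise-identical datasets", {
  cfg <- small_sim_config()
  d1 <- simulate_experiment(cfg)
  d2 <- simulate_experiment(cfg)
  expect_identical(d1$expression$matrix, d2$expression$matrix)
  expect_identical(d1$chemostat$expression, d2$chemostat$expression)
  expect_identical(d1$loci, d2$loci)
})

test_that("different seeds change the noise but not the truth structure", {
  d1 <- simulate_experiment(small_sim_config(rng_seed = 1))
  d2 <- simulate_experiment(small_sim_config(rng_seed = 2))
  expect_false(identical(d1$expression$matrix, d2$expression$matrix))
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$loci, d2$loci)
  expect_identical(d1$annotations, d2$annotations)
})

test_that("planted induced-minus-control means obey the law of large numbers", {
  cfg <- sim_config(n_genes = 450, n_scaffolds = 3, n_clusters = 1,
                    cluster_sizes = 250L,
                    effect_log2 = matrix(2, 1, 4),
                    time_profiles = "step", noise_sd = 0.5,
                    n_regions = 1, region_span = 4, n_regulators = 1,
                    n_reference = 1, rng_seed = 11)
  ds <- simulate_experiment(cfg)
  des <- ds$expression$design
  members <- names(ds$truth$cluster)[ds$truth$cluster == 1]
  diffs <- c()
  for (s in cfg$substrates) {
    ind <- des$sample_id[des$role == "induced" & des$substrate == s &
                           des$time_h == 6]
    ctl <- des$sample_id[des$role == "control" & des$time_h == 6]
    diffs <- c(diffs, rowMeans(ds$expression$matrix[members, ind]) -
                 rowMeans(ds$expression$matrix[members, ctl]))
  }
  n_cells <- length(diffs)  # 1000 member-gene cells
  expect_gte(n_cells, 1000)
  bound <- 3 * 2 * 0.5 / sqrt(4 * n_cells)
  expect_lt(abs(mean(diffs) - 2), bound)
})

test_that("gene counts agree across expression, loci and annotations", {
  ds <- simulate_experiment(small_sim_config())
  expect_equal(nrow(ds$expression$matrix), nrow(ds$loci))
  expect_setequal(ds$loci$gene_id, rownames(ds$expression$matrix))
  expect_setequal(unique(ds$annotations$gene_id), ds$loci$gene_id)
  # loci are unique, sorted and non-overlapping within scaffolds
  expect_false(anyDuplicated(ds$loci$gene_id) > 0)
  for (sc in unique(ds$loci$scaffold)) {
    sub <- ds$loci[ds$loci$scaffold == sc, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(utils::head(sub$end, -1) < utils::tail(sub$start, -1)))
  }
})

test_that("planted regulators carry the full evidence signature", {
  ds <- simulate_experiment(small_sim_config())
  regs <- ds$truth$regulators
  ann <- ds$annotations
  expect_true(all(regs %in% ann$gene_id[ann$class_label == "fungal_C6_TF"]))
  expect_true(all(ds$truth$cluster[regs] > 0))
  region_genes <- unlist(strsplit(ds$truth$regions$gene_ids, ","))
  expect_true(all(regs %in% region_genes))
  expect_true(all(regs %in% ds$chemostat$truth$gene_id))
  expect_true(all(ds$truth$proteome_flags[regs] != 0))
})

test_that("planted region extents are recoverable from true labels", {
  ds <- simulate_experiment(small_sim_config())
  assignment <- data.frame(gene_id = names(ds$truth$cluster),
                           cluster = unname(ds$truth$cluster))
  loci <- order_genes(ds$loci)
  patches <- find_adjacent_patches(loci, assignment,
                                   exclude_clusters = 0L)
  windowed <- find_coregulated_regions(loci, assignment,
                                       exclude_clusters = 0L)
  for (i in seq_len(nrow(ds$truth$regions))) {
    genes <- sort(strsplit(ds$truth$regions$gene_ids[i], ",")[[1]])
    p_sets <- sort(vapply(strsplit(patches$gene_ids, ","),
                          function(g) paste(sort(g), collapse = ","),
                          character(1)))
    w_sets <- sort(vapply(strsplit(windowed$gene_ids, ","),
                          function(g) paste(sort(g), collapse = ","),
                          character(1)))
    key <- paste(genes, collapse = ",")
    expect_true(key %in% p_sets)
    expect_true(key %in% w_sets)
  }
})

test_that("impossible region layouts are rejected, not truncated", {
  expect_error(
    simulate_experiment(sim_config(n_genes = 40, n_scaffolds = 1,
                                   cluster_sizes = rep(6L, 6L),
                                   n_regions = 6, region_span = 5,
                                   n_regulators = 6, n_reference = 6)),
    "cannot fit")
})

test_that("noise-free chemostat correlations are exactly +/-1", {
  cfg <- small_sim_config(chemostat_noise_sd = 0)
  chem <- simulate_chemostat(cfg)
  expect_gte(length(chem$rates), 3)
  z <- chem$expression[chem$truth$gene_id, ]
  r <- suppressWarnings(as.numeric(cor(t(z), chem$rates)))
  expect_equal(r, chem$truth$sign, tolerance = 1e-12)
})

test_that("degenerate chemostat designs are rejected", {
  expect_error(simulate_chemostat(small_sim_config(
    rate_profile = c(a = 1, b = 2))), ">= 3 conditions")
  expect_error(simulate_chemostat(small_sim_config(
    rate_profile = c(a = 1, b = 1, c = 1))), "equal")
})
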