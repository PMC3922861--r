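test_that("a gene with identical groups is an exact null", {
  ind <- rbind(c(8, 8, 8, 8), matrix(rnorm(12, 8), 3, 4))
  ctl <- rbind(c(8, 8, 8, 8), matrix(rnorm(12, 8), 3, 4))
  tbl <- fit_contrasts(toy_dataset(ind, ctl))
  row <- tbl[tbl$gene_id == "g001", ]
  expect_equal(row$log2fc, 0)
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
  tbl <- call_differential(tbl)
  expect_equal(tbl$call[tbl$gene_id == "g001"], 0L)
})

test_that("with zero prior df the statistic is the textbook pooled t", {
  x <- c(8.1, 8.4, 7.9, 8.3)
  y <- c(7.6, 7.8, 7.5, 7.7)
  ind <- rbind(x, matrix(rnorm(28, 8, 0.4), 7, 4))
  ctl <- rbind(y, matrix(rnorm(28, 8, 0.4), 7, 4))
  tbl <- fit_contrasts(toy_dataset(ind, ctl), prior_df = 0)
  expect_equal(tbl$t[tbl$gene_id == "g001"], oracle_pooled_t(x, y),
               tolerance = 1e-10)
  expect_equal(tbl$p[tbl$gene_id == "g001"],
               2 * pt(-abs(oracle_pooled_t(x, y)), df = 6),
               tolerance = 1e-10)
})

test_that("moderated t matches limma on shared data", {
  set.seed(42)
  n <- 400
  sd_g <- sqrt(1 / rgamma(n, shape = 3, rate = 0.3))  # heterogeneous
  ind <- matrix(rnorm(n * 4, 8, sd_g), n, 4)
  ctl <- matrix(rnorm(n * 4, 8, sd_g), n, 4)
  ds <- toy_dataset(ind, ctl)
  tbl <- fit_contrasts(ds)
  design <- cbind(ctl = 1, ind = rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(ds$matrix, design))
  expect_equal(attr(tbl, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tbl, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(tbl$t, unname(fit$t[, "ind"]), tolerance = 1e-8)
  expect_equal(tbl$p, unname(fit$p.value[, "ind"]), tolerance = 1e-8)
})

test_that("calls follow the significance and fold-change cutoffs", {
  tbl <- fake_contrast_table(p = c(0.005, 0.005, 0.5, 0.005, 0.009),
                             log2fc = c(0.5, 0.3, 3.0, -0.5, 0.41))
  tbl <- call_differential(tbl)
  expect_equal(tbl$call, c(1L, 0L, 0L, -1L, 1L))
  smry <- attr(tbl, "summary")
  expect_equal(smry$n_up, 2L)
  expect_equal(smry$n_down, 1L)
  expect_error(call_differential(tbl, p_cut = 0), "positive")
  expect_error(call_differential(tbl, lfc_cut = -1), "positive")
})

test_that("relaxing either cutoff never removes calls", {
  set.seed(5)
  tbl <- fake_contrast_table(p = runif(200), log2fc = rnorm(200))
  n_calls <- function(p_cut, lfc_cut)
    sum(call_differential(tbl, p_cut, lfc_cut)$call != 0)
  for (i in 1:10) {
    p1 <- runif(1, 0.001, 0.5); p2 <- p1 * runif(1, 1, 5)
    l1 <- runif(1, 0.1, 1); l2 <- l1 * runif(1, 0.2, 1)
    expect_lte(n_calls(p1, l1), n_calls(p2, l1))
    expect_lte(n_calls(p1, l1), n_calls(p1, l2))
  }
})

test_that("adding a constant to a gene leaves log2fc and t unchanged", {
  set.seed(8)
  ind <- matrix(rnorm(40, 8), 10, 4)
  ctl <- matrix(rnorm(40, 8), 10, 4)
  t1 <- fit_contrasts(toy_dataset(ind, ctl))
  ind2 <- ind; ctl2 <- ctl
  ind2[3, ] <- ind2[3, ] + 5; ctl2[3, ] <- ctl2[3, ] + 5
  t2 <- fit_contrasts(toy_dataset(ind2, ctl2))
  expect_equal(t1$log2fc[3], t2$log2fc[3], tolerance = 1e-12)
  expect_equal(t1$t[3], t2$t[3], tolerance = 1e-12)
})

test_that("large prior df approaches the common-variance z statistic", {
  set.seed(9)
  ind <- matrix(rnorm(200, 8, 0.5), 50, 4)
  ctl <- matrix(rnorm(200, 8, 0.5), 50, 4)
  ds <- toy_dataset(ind, ctl)
  tbl <- fit_contrasts(ds, prior_df = 1e9)
  s0 <- attr(tbl, "s0_sq")
  expect_equal(tbl$t, tbl$log2fc / sqrt(s0 * 0.5), tolerance = 1e-6)
})

test_that("cells with too few replicates are flagged, not zeroed", {
  m <- matrix(rnorm(30, 8), 5, 6)
  rownames(m) <- sprintf("g%d", 1:5)
  colnames(m) <- sprintf("s%d", 1:6)
  design <- data.frame(
    sample_id = colnames(m),
    substrate = c("avicel", "avicel", "wheat", rep("control", 3)),
    time_h = 6, replicate = c(1, 2, 1, 1, 2, 3),
    role = c("induced", "induced", "induced", rep("control", 3)),
    stringsAsFactors = FALSE)
  tbl <- fit_contrasts(expression_dataset(m, design))
  wheat <- tbl[tbl$substrate == "wheat", ]
  expect_false(any(wheat$available))
  expect_true(all(is.na(wheat$p)))
  expect_true(all(is.na(wheat$call)))
  avicel <- tbl[tbl$substrate == "avicel", ]
  expect_true(all(avicel$available))
})

test_that("induction breadth counts substrates with an induced call", {
  cfg <- sim_config(n_genes = 80, n_scaffolds = 1, n_clusters = 1,
                    cluster_sizes = 20L,
                    effect_log2 = matrix(c(2, 2, 0, 0), 1, 4),
                    time_profiles = "step", noise_sd = 0.05,
                    n_regions = 1, region_span = 3, n_regulators = 1,
                    n_reference = 1, rng_seed = 2)
  ds <- simulate_experiment(cfg)
  tbl <- call_differential(fit_contrasts(ds$expression))
  b <- induction_breadth(tbl)
  members <- names(ds$truth$cluster)[ds$truth$cluster == 1]
  expect_true(all(b[members] == 2L))
  expect_true(all(b[setdiff(names(b), members)] == 0L))
  # repression never counts towards breadth
  tbl2 <- fake_contrast_table(p = rep(0.001, 4), log2fc = rep(-2, 4),
                              gene_id = rep("gX", 4),
                              substrate = c("a", "b", "c", "d"))
  tbl2 <- call_differential(tbl2)
  expect_equal(unname(induction_breadth(tbl2)["gX"]), 0L)
})
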