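# Shared fixture builders (everything generated in code).

# a small but complete simulation config, cheap enough for most tests
small_sim_config <- function(...) {
  args <- list(n_genes = 300L, n_scaffolds = 3L,
               cluster_sizes = rep(30L, 6L),
               n_regions = 4L, region_span = 5L,
               n_regulators = 8L, n_reference = 8L,
               rng_seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# hand-built contrast table for call/selection logic tests
fake_contrast_table <- function(p, log2fc, gene_id = NULL,
                                substrate = "avicel", time_h = 6) {
  n <- length(p)
  df <- data.frame(gene_id = gene_id %||% sprintf("g%03d", seq_len(n)),
                   substrate = rep_len(substrate, n),
                   time_h = rep_len(time_h, n),
                   log2fc = log2fc, s2 = 0.1, df = 6, n_i = 4, n_c = 4,
                   available = TRUE, t = log2fc / 0.1, p = p, p_adj = p,
                   call = 0L, stringsAsFactors = FALSE)
  class(df) <- c("contrast_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-group expression dataset with explicit values per gene
toy_dataset <- function(induced, control, substrate = "avicel",
                        time_h = 6) {
  stopifnot(nrow(induced) == nrow(control))
  n <- nrow(induced)
  ids <- sprintf("g%03d", seq_len(n))
  m <- cbind(induced, control)
  rownames(m) <- ids
  colnames(m) <- c(sprintf("ind_%d", seq_len(ncol(induced))),
                   sprintf("ctl_%d", seq_len(ncol(control))))
  design <- data.frame(
    sample_id = colnames(m),
    substrate = c(rep(substrate, ncol(induced)),
                  rep("control", ncol(control))),
    time_h = time_h,
    replicate = c(seq_len(ncol(induced)), seq_len(ncol(control))),
    role = c(rep("induced", ncol(induced)),
             rep("control", ncol(control))),
    stringsAsFactors = FALSE)
  expression_dataset(m, design)
}

# random loci table: one scaffold, n genes in random order on disk
random_loci <- function(n, scaffold = "sc1", shuffle = TRUE) {
  starts <- seq_len(n) * 1500L - 1499L
  df <- data.frame(gene_id = sprintf("%s_g%03d", scaffold, seq_len(n)),
                   scaffold = scaffold,
                   start = starts, end = starts + 999L,
                   strand = rep_len(c("+", "-"), n),
                   stringsAsFactors = FALSE)
  if (shuffle) df <- df[sample.int(n), ]
  df
}
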