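#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic induction experiment.
#
# Produces the full input bundle (expression + design, genome GFF3,
# domain annotations, reference genes, chemostat rates/expression, and
# the planted truth) under results/inputs/.

suppressPackageStartupMessages(library(cazyscreen))

seed <- 1L
results <- "results"

config <- sim_config(rng_seed = seed)
dataset <- simulate_experiment(config)
paths <- write_synthetic_inputs(dataset, file.path(results, "inputs"))

cat("genes:", nrow(dataset$loci),
    " samples:", ncol(dataset$expression$matrix),
    " planted regulators:", length(dataset$truth$regulators), "\n")
cat("wrote:\n"); invisible(lapply(paths, function(p) cat(" ", p, "\n")))
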