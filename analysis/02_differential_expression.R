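#!/usr/bin/env Rscript
# Stage 2 — moderated two-group contrasts per (substrate, time point)
# against the time-matched uninduced control, then induction calls at
# P < 0.01 and |log2FC| > 0.4.

suppressPackageStartupMessages(library(cazyscreen))

results <- "results"

ds <- read_expression_dataset(file.path(results, "inputs", "expression.tsv"),
                              file.path(results, "inputs", "design.tsv"))
contrasts <- call_differential(fit_contrasts(ds), p_cut = 0.01,
                               lfc_cut = 0.4)
write_contrasts_tsv(contrasts, file.path(results, "contrasts.tsv"))

breadth <- induction_breadth(contrasts)
write_tsv(data.frame(gene_id = names(breadth),
                     induction_breadth = as.integer(breadth)),
          file.path(results, "induction_breadth.tsv"))

cat("prior df:", attr(contrasts, "d0"),
    " prior variance:", attr(contrasts, "s0_sq"), "\n")
print(attr(contrasts, "summary"))
cat("genes induced on >= 3 substrates:", sum(breadth >= 3), "\n")
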