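#!/usr/bin/env Rscript
# Stage 7 — assemble the five evidence criteria per gene (broad
# induction, co-clustering with the reference genes, production-rate
# correlation, proteome support, co-localization) and select
# regulatory-class candidates meeting at least three of them.

suppressPackageStartupMessages(library(cazyscreen))

results <- "results"

breadth_df <- read_tsv(file.path(results, "induction_breadth.tsv"))
breadth <- setNames(as.integer(breadth_df$induction_breadth),
                    breadth_df$gene_id)
co_clustered <- readLines(file.path(results, "co_clustered_genes.txt"))
corr <- read_tsv(file.path(results, "correlations.tsv"))
class(corr) <- c("correlation_screen", "data.frame")
regions <- read_regions_tsv(file.path(results, "regions.tsv"))
coloc <- read_tsv(file.path(results, "regulator_colocation.tsv"))
ann <- read_annotations_tsv(file.path(results, "inputs", "annotations.tsv"))
truth <- read_truth_json(file.path(results, "inputs", "truth.json"))

universe <- names(breadth)
region_genes <- unique(unlist(strsplit(regions$gene_ids, ",", fixed = TRUE)))
near_ids <- coloc$gene_id[coloc$near_cazy_or_transporter]
regulatory_ids <- unique(ann$gene_id[ann$class_label == "fungal_C6_TF"])
proteome <- truth$proteome_flags[universe]

evidence <- build_evidence(universe = universe, breadth = breadth,
                           co_clustered = co_clustered, correlation = corr,
                           region_gene_ids = region_genes,
                           near_ids = near_ids,
                           regulatory_class_ids = regulatory_ids,
                           proteome_flags = proteome, breadth_min = 3)
report <- select_candidates(evidence, min_criteria = 3)
write_tsv(as.data.frame(evidence), file.path(results, "evidence.tsv"))
write_tsv(as.data.frame(report), file.path(results, "candidates.tsv"))

sel <- report$gene_id[report$selected]
planted <- truth$regulators
cat("selected candidates:", length(sel), "\n")
cat("recall of planted regulators:",
    round(length(intersect(sel, planted)) / length(planted), 3),
    " precision:",
    round(length(intersect(sel, planted)) / max(1, length(sel)), 3), "\n")
print(head(as.data.frame(report)[report$selected,
      c("gene_id", "criteria_met", "score", "rank")], 10))
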