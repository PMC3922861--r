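#!/usr/bin/env Rscript
# Stage 4 — locate the clusters holding the known cellulase/
# hemicellulase reference genes, pool their members, and test every
# annotation class for over-representation (hypergeometric upper tail).

suppressPackageStartupMessages(library(cazyscreen))

results <- "results"

assignment <- read_clusters_tsv(file.path(results, "clusters.tsv"))
refs <- readLines(file.path(results, "inputs", "reference_genes.txt"))
ann <- read_annotations_tsv(file.path(results, "inputs", "annotations.tsv"))

ref <- reference_clusters(assignment,
                          intersect(refs, assignment$gene_id),
                          min_fraction = 0.9)
writeLines(ref$co_clustered, file.path(results, "co_clustered_genes.txt"))

enr <- class_enrichment_all(ref$co_clustered, ann, assignment$gene_id)
write_tsv(enr, file.path(results, "enrichment.tsv"))

cat("reference-enriched clusters:", paste(ref$clusters, collapse = ", "),
    "\nco-clustered genes:", length(ref$co_clustered), "\n")
print(head(as.data.frame(enr)))
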