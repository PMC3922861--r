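#!/usr/bin/env Rscript
# Stage 5 — scan each scaffold for co-regulated regions: >= 3 genes of
# one expression cluster within a 9-gene window, successive members
# <= 5 genes apart; plus strictly adjacent patches (runs >= 3). Then
# annotate the regulatory-class genes with their immediate neighbors.

suppressPackageStartupMessages(library(cazyscreen))

results <- "results"

loci <- read_gff3(file.path(results, "inputs", "genes.gff3"))
assignment <- read_clusters_tsv(file.path(results, "clusters.tsv"))
ann <- read_annotations_tsv(file.path(results, "inputs", "annotations.tsv"))

regions <- find_coregulated_regions(loci, assignment,
                                    window = 9, min_members = 3,
                                    max_gap = 5)
patches <- find_adjacent_patches(loci, assignment, min_run = 3)
all_regions <- rbind(as.data.frame(regions), as.data.frame(patches))
write_tsv(all_regions, file.path(results, "regions.tsv"))
write_regions_bed(all_regions, file.path(results, "regions.bed"))

regulatory_ids <- unique(ann$gene_id[ann$class_label == "fungal_C6_TF"])
nbr <- annotate_neighbors(loci, regions, regulatory_ids,
                          annotation_roles(ann, "fungal_C6_TF"), flank = 1)
write_tsv(nbr$neighbors, file.path(results, "regulator_neighbors.tsv"))
write_tsv(nbr$candidates, file.path(results, "regulator_colocation.tsv"))

cat("windowed regions:", nrow(regions),
    " adjacent patches:", nrow(patches), "\n")
cat("regulatory-class genes inside a region:",
    sum(nbr$candidates$in_region), "of", nrow(nbr$candidates), "\n")
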