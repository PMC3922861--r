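# Readers and writers for every artifact the pipeline touches. All
# tabular files are TSV with explicit headers; lines starting with '#'
# carry provenance metadata (package version, config hash, seed) and are
# skipped on read. Genome coordinates travel as GFF3 (1-based inclusive)
# or BED (0-based half-open), both normalized to the internal 1-based
# inclusive convention through rtracklayer.

#' Write / read a plain TSV table
#'
#' The workhorse behind every tabular artifact: headers on the first
#' non-comment line, optional `# key=value` provenance lines on top,
#' no quoting, no row names.
#'
#' @param df data.frame to write
#' @param path file path
#' @param meta optional named list written as `# key=value` header lines
#' @return `write_tsv` the path, invisibly; `read_tsv` a data.frame
#' @export
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s=%s", names(meta), unlist(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read an expression matrix
#'
#' TSV dialect: first column `gene_id`, one column per sample, log2
#' signals.
#'
#' @param matrix numeric gene x sample matrix with dimnames
#' @param path file path
#' @param meta optional named list written as `# key=value` header lines
#' @return `write_expression_tsv` the path, invisibly;
#'   `read_expression_tsv` the numeric matrix
#' @export
write_expression_tsv <- function(matrix, path, meta = NULL) {
  df <- data.frame(gene_id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, meta)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene_id") stop("expression TSV must start with gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df$gene_id
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing expression value at gene '%s', sample '%s' in %s",
                 rownames(m)[idx[1]], colnames(m)[idx[2]], path))
  }
  m
}

#' Write / read a sample design table
#'
#' Columns: `sample_id`, `substrate`, `time_h`, `replicate`, `role`
#' (`induced`/`control`).
#' @param design data.frame
#' @inheritParams write_expression_tsv
#' @return the path / the validated data.frame
#' @export
write_design_tsv <- function(design, path, meta = NULL) {
  write_tsv(design, path, meta)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "substrate", "time_h", "replicate", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design TSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$role %in% c("induced", "control")))
  if (length(bad))
    stop("invalid role at line ", bad[1] + 1L, " of ", path)
  df
}

#' Read an expression dataset from its TSV pair
#'
#' @param expression_path expression TSV (see [write_expression_tsv()])
#' @param design_path design TSV (see [write_design_tsv()])
#' @return an [expression_dataset()]
#' @export
read_expression_dataset <- function(expression_path, design_path) {
  expression_dataset(read_expression_tsv(expression_path),
                     read_design_tsv(design_path))
}

#' Write / read the gene annotation table
#'
#' Long format: `gene_id`, `domain_id`, `class_label`; a gene may appear
#' on several rows (one per class).
#' @param annotations data.frame
#' @inheritParams write_expression_tsv
#' @return the path / the data.frame
#' @export
write_annotations_tsv <- function(annotations, path, meta = NULL) {
  write_tsv(annotations, path, meta)
}

#' @rdname write_annotations_tsv
#' @export
read_annotations_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "domain_id", "class_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation TSV missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write / read the chemostat rate table
#'
#' Columns: `condition`, `rate` (specific protein production rate).
#' @param rates named numeric vector
#' @inheritParams write_expression_tsv
#' @return the path / a named numeric vector
#' @export
write_rates_tsv <- function(rates, path, meta = NULL) {
  write_tsv(data.frame(condition = names(rates), rate = as.numeric(rates),
                       stringsAsFactors = FALSE), path, meta)
}

#' @rdname write_rates_tsv
#' @export
read_rates_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("condition", "rate") %in% names(df)))
    stop("rate TSV needs columns condition, rate")
  if (!is.numeric(df$rate)) stop("non-numeric rates in ", path)
  stats::setNames(df$rate, df$condition)
}

loci_to_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$scaffold,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = ifelse(loci$strand %in% c("+", "-"), loci$strand, "*"),
    type = "gene",
    ID = loci$gene_id,
    Name = loci$gene_id)
}

granges_to_loci <- function(gr, id_field = c("ID", "Name", "name")) {
  md <- S4Vectors::mcols(gr)
  id <- NULL
  for (f in id_field) {
    if (f %in% names(md) && !all(is.na(md[[f]]))) { id <- md[[f]]; break }
  }
  if (is.null(id)) stop("no gene identifier field in annotation track")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(gene_id = as.character(id),
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Write / read gene loci as GFF3
#'
#' Genes are written as `gene` features with `ID`/`Name` attributes,
#' 1-based inclusive per the GFF3 specification.
#' @param loci data.frame with `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`
#' @param path file path
#' @return the path / an ordered [order_genes()] result
#' @export
write_gff3 <- function(loci, path) {
  rtracklayer::export(loci_to_granges(loci), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  order_genes(granges_to_loci(gr))
}

#' Read gene loci from a BED file
#'
#' BED is 0-based half-open on disk; rtracklayer converts to the
#' internal 1-based inclusive convention, so a BED line `100 200` and a
#' GFF3 gene at `101..200` describe the same locus.
#' @param path BED file with the gene id in the name column
#' @return an ordered [order_genes()] result
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  order_genes(granges_to_loci(gr, id_field = c("name", "Name", "ID")))
}

#' Write gene loci as BED6
#' @inheritParams write_gff3
#' @export
write_bed <- function(loci, path) {
  gr <- loci_to_granges(loci)
  # the BED exporter takes the feature name from the `name` column
  gr$name <- loci$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write / read a contrast table
#' @param table a `contrast_table`
#' @inheritParams write_expression_tsv
#' @return the path / the `contrast_table` (prior attributes restored
#'   from the header when present)
#' @export
write_contrasts_tsv <- function(table, path, meta = NULL) {
  meta <- c(meta, list(d0 = format(attr(table, "d0"), digits = 17),
                       s0_sq = format(attr(table, "s0_sq"), digits = 17)))
  write_tsv(as.data.frame(table), path, meta)
}

#' @rdname write_contrasts_tsv
#' @export
read_contrasts_tsv <- function(path) {
  df <- read_tsv(path)
  hdr <- grep("^# ", readLines(path, n = 50L), value = TRUE)
  for (key in c("d0", "s0_sq")) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln))
      attr(df, key) <- as.numeric(sub(paste0("^# ", key, "="), "", ln[1]))
  }
  class(df) <- c("contrast_table", "data.frame")
  df
}

#' Write / read a cluster assignment table
#' @param assignment an [assign_clusters()] result
#' @inheritParams write_expression_tsv
#' @export
write_clusters_tsv <- function(assignment, path, meta = NULL) {
  write_tsv(as.data.frame(assignment), path, meta)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "cluster", "membership", "core")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cluster TSV missing columns: ", paste(miss, collapse = ", "))
  class(df) <- c("cluster_assignment", "data.frame")
  df
}

#' Read region calls written by the pipeline
#' @param path regions TSV
#' @return a `region_calls` data.frame
#' @export
read_regions_tsv <- function(path) {
  df <- read_tsv(path)
  class(df) <- c("region_calls", "data.frame")
  df
}

#' Write every input artifact of a synthetic dataset
#'
#' Writes the standard pipeline inputs: expression and design TSV, GFF3
#' gene models, annotation TSV, reference gene list, chemostat rate and
#' expression TSV, and the ground-truth JSON.
#'
#' @param dataset a [simulate_experiment()] result
#' @param dir output directory (created if needed)
#' @return invisibly, a named vector of file paths
#' @export
write_synthetic_inputs <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = dataset$config$rng_seed)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    genes = file.path(dir, "genes.gff3"),
    annotations = file.path(dir, "annotations.tsv"),
    reference = file.path(dir, "reference_genes.txt"),
    rates = file.path(dir, "rates.tsv"),
    chemostat = file.path(dir, "chemostat_expression.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression_tsv(dataset$expression$matrix, paths["expression"], meta)
  write_design_tsv(dataset$expression$design, paths["design"], meta)
  write_gff3(dataset$loci, paths["genes"])
  write_annotations_tsv(dataset$annotations, paths["annotations"], meta)
  writeLines(dataset$reference_genes, paths["reference"])
  write_rates_tsv(dataset$chemostat$rates, paths["rates"], meta)
  write_expression_tsv(dataset$chemostat$expression, paths["chemostat"], meta)
  truth <- dataset$truth
  jsonlite::write_json(
    list(cluster = as.list(truth$cluster),
         regions = truth$regions,
         regulators = truth$regulators,
         roles = as.list(truth$roles),
         proteome_flags = as.list(truth$proteome_flags)),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Read the ground-truth JSON of a synthetic dataset
#' @param path truth.json path
#' @return list with `cluster`, `regions`, `regulators`, `roles`,
#'   `proteome_flags`
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cluster <- unlist(x$cluster)
  x$roles <- unlist(x$roles)
  x$proteome_flags <- unlist(x$proteome_flags)
  x
}
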