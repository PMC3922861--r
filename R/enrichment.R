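# Functional-class over-representation via the hypergeometric
# distribution (e.g. fungal Zn2-C6 transcription-factor domains among
# co-clustered genes).

#' Hypergeometric class enrichment
#'
#' Tests whether a functional class is over-represented in a gene set
#' relative to a universe: with `N` universe genes of which `K` carry the
#' class, and a set of `n` genes of which `k` carry it, the upper-tail
#' probability `P(X >= k)` of the hypergeometric distribution is reported
#' together with the fold enrichment `(k/n) / (K/N)`.
#'
#' @param gene_set character vector, a subset of `universe`
#' @param class_label class to test, as used in `annotation$class_label`
#' @param annotation data.frame with columns `gene_id`, `class_label`
#'   (long format; a gene may carry several classes)
#' @param universe character vector of all genes considered
#' @return data.frame row of class `"enrichment_result"`: `class`, `N`,
#'   `K`, `n`, `k`, `fold`, `p`
#' @examples
#' ann <- data.frame(gene_id = letters[1:5], class_label = "TF")
#' class_enrichment(letters[1:4], "TF", ann, letters[1:10])
#' @export
class_enrichment <- function(gene_set, class_label, annotation, universe) {
  if (length(universe) == 0L) stop("empty universe")
  if (length(gene_set) == 0L) stop("empty gene set")
  if (anyDuplicated(universe)) universe <- unique(universe)
  gene_set <- unique(gene_set)
  bad <- setdiff(gene_set, universe)
  if (length(bad))
    stop("gene set not contained in universe: ", paste(bad, collapse = ", "))
  stopifnot(all(c("gene_id", "class_label") %in% names(annotation)))
  class_genes <- unique(annotation$gene_id[annotation$class_label == class_label])
  class_genes <- intersect(class_genes, universe)
  N <- length(universe)
  K <- length(class_genes)
  n <- length(gene_set)
  k <- length(intersect(gene_set, class_genes))
  p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fold <- if (K == 0L) 0 else (k / n) / (K / N)
  out <- data.frame(class = class_label, N = N, K = K, n = n, k = k,
                    fold = fold, p = p, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment over every annotated class
#'
#' Runs [class_enrichment()] for each class in the annotation vocabulary
#' and appends a Benjamini-Hochberg adjusted p-value across classes. The
#' raw p remains the primary quantity; the adjusted column is
#' informational.
#'
#' @inheritParams class_enrichment
#' @param classes classes to test; defaults to all in `annotation`
#' @return data.frame with one row per class, ordered by raw `p`
#' @export
class_enrichment_all <- function(gene_set, annotation, universe,
                                 classes = NULL) {
  classes <- classes %||% setdiff(unique(annotation$class_label), "none")
  rows <- lapply(classes, function(cl)
    class_enrichment(gene_set, cl, annotation, universe))
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
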