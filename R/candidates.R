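# Integration of the evidence streams into the multi-criteria candidate
# screen: induction breadth, co-clustering with the characterized
# cellulase/hemicellulase genes, correlation with the specific protein
# production rate, proteome support, and genomic co-localization.

#' Assemble the per-gene evidence table
#'
#' Combines the upstream module outputs over one gene universe. The five
#' screen criteria are: induction on at least `breadth_min` substrates;
#' co-clustering with the reference genes; passing the production-rate
#' correlation screen; a non-zero proteome-evidence flag; and genomic
#' co-localization (membership in a co-regulated region OR adjacency to
#' a CAZy/transporter gene).
#'
#' @param universe character vector of all gene ids
#' @param breadth named integer vector from [induction_breadth()]
#' @param co_clustered character vector of co-clustered gene ids (from
#'   [reference_clusters()])
#' @param correlation a [production_correlation()] result
#' @param region_gene_ids gene ids inside detected co-regulated regions
#' @param near_ids gene ids adjacent to a CAZy or transporter gene
#' @param regulatory_class_ids gene ids carrying a configured regulatory
#'   domain class
#' @param proteome_flags named integer vector in {-1, 0, +1}; missing
#'   genes default to 0
#' @param breadth_min substrates required for the induction criterion,
#'   default 3
#' @return data.frame of class `"evidence_table"`, one row per universe
#'   gene: `gene_id`, `regulatory_class`, `induction_breadth`,
#'   `induction_pass`, `co_clustered`, `corr_pass`, `corr_sign`,
#'   `proteome_flag`, `proteome_pass`, `in_region`,
#'   `near_cazy_or_transporter`, `colocalized`
#' @export
build_evidence <- function(universe, breadth, co_clustered, correlation,
                           region_gene_ids, near_ids, regulatory_class_ids,
                           proteome_flags = NULL, breadth_min = 3L) {
  universe <- unique(universe)
  check_universe <- function(ids, what) {
    bad <- setdiff(ids, universe)
    if (length(bad))
      stop(what, " outside the gene universe: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  check_universe(names(breadth), "breadth genes")
  check_universe(co_clustered, "co-clustered genes")
  check_universe(correlation$gene_id, "correlation genes")
  check_universe(region_gene_ids, "region genes")
  check_universe(near_ids, "neighbor genes")
  check_universe(regulatory_class_ids, "regulatory-class genes")
  if (is.null(proteome_flags))
    proteome_flags <- stats::setNames(integer(length(universe)), universe)
  check_universe(names(proteome_flags), "proteome genes")
  if (!all(proteome_flags %in% c(-1L, 0L, 1L)))
    stop("proteome_flags must be -1, 0 or +1")

  b <- stats::setNames(integer(length(universe)), universe)
  b[names(breadth)] <- as.integer(breadth)
  pf <- stats::setNames(integer(length(universe)), universe)
  pf[names(proteome_flags)] <- as.integer(proteome_flags)
  rmap <- stats::setNames(rep(NA_real_, length(universe)), universe)
  rmap[correlation$gene_id] <- correlation$r
  cp <- stats::setNames(rep(FALSE, length(universe)), universe)
  cp[correlation$gene_id] <- correlation$pass
  cs <- stats::setNames(integer(length(universe)), universe)
  cs[correlation$gene_id] <- correlation$sign

  out <- data.frame(
    gene_id = universe,
    regulatory_class = universe %in% regulatory_class_ids,
    induction_breadth = unname(b),
    induction_pass = unname(b) >= breadth_min,
    co_clustered = universe %in% co_clustered,
    corr_r = unname(rmap),
    corr_pass = unname(cp),
    corr_sign = unname(cs),
    proteome_flag = unname(pf),
    proteome_pass = unname(pf) != 0L,
    in_region = universe %in% region_gene_ids,
    near_cazy_or_transporter = universe %in% near_ids,
    stringsAsFactors = FALSE)
  out$colocalized <- out$in_region | out$near_cazy_or_transporter
  class(out) <- c("evidence_table", "data.frame")
  out
}

#' Select and rank candidate regulator genes
#'
#' Applies the multi-criteria screen to an evidence table. By default a
#' candidate must carry a regulatory domain class (the screen focuses on
#' genes encoding putative transcription factors) and fulfil at least
#' `min_criteria` of the five criteria (induction breadth,
#' co-clustering, rate correlation, proteome support, co-localization).
#' Genes are ranked by weighted criteria score, ties broken by criteria
#' count and then gene id.
#'
#' @param evidence an [build_evidence()] result
#' @param min_criteria criteria required for selection, default 3
#' @param require_regulatory_class gate on the regulatory domain class,
#'   default `TRUE`
#' @param weights numeric length-5 vector of criterion weights in the
#'   order induction, co-clustering, correlation, proteome,
#'   co-localization; default uniform
#' @return data.frame of class `"candidate_report"`: the per-criterion
#'   breakdown plus `criteria_met`, `score`, `selected` and `rank`
#'   (1 = best), ordered by rank
#' @export
select_candidates <- function(evidence, min_criteria = 3L,
                              require_regulatory_class = TRUE,
                              weights = rep(1, 5)) {
  stopifnot(inherits(evidence, "evidence_table"))
  if (length(weights) != 5L || any(weights < 0))
    stop("weights must be 5 non-negative numbers")
  if (min_criteria > 5L)
    stop("min_criteria exceeds the number of configured criteria (5)")
  crit <- cbind(induction = evidence$induction_pass,
                co_clustered = evidence$co_clustered,
                correlation = evidence$corr_pass,
                proteome = evidence$proteome_pass,
                colocalization = evidence$colocalized)
  out <- evidence
  out$criteria_met <- as.integer(rowSums(crit))
  out$score <- as.numeric(crit %*% weights)
  gate <- if (require_regulatory_class) evidence$regulatory_class else TRUE
  out$selected <- gate & out$criteria_met >= min_criteria
  ord <- order(!gate, -out$score, -out$criteria_met, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "min_criteria") <- min_criteria
  class(out) <- c("candidate_report", "data.frame")
  out
}
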