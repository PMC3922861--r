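# Detection of genomic regions enriched in co-regulated genes: the
# windowed rule (>= 3 members of one expression cluster within a window
# of nine neighboring genes, successive members at most five genes
# apart) and the adjacency rule (patches of >= 3 rank-consecutive
# same-cluster genes).

#' Order gene loci along their scaffolds
#'
#' Validates loci and assigns each gene its 0-based rank in the
#' start-sorted gene order of its scaffold. Strand is ignored for
#' ordering.
#'
#' @param loci data.frame with columns `gene_id`, `scaffold`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates)
#' @return the loci sorted by (scaffold, start) with an integer `rank`
#'   column, class `"gene_loci"`
#' @export
order_genes <- function(loci) {
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  miss <- setdiff(need, names(loci))
  if (length(miss))
    stop("loci missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(loci$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(loci$gene_id[duplicated(loci$gene_id)]), collapse = ", "))
  if (any(loci$end < loci$start))
    stop("inverted intervals for: ",
         paste(loci$gene_id[loci$end < loci$start], collapse = ", "))
  loci <- loci[order(loci$scaffold, loci$start), , drop = FALSE]
  loci$rank <- as.integer(stats::ave(loci$start, loci$scaffold,
                                     FUN = function(x) seq_along(x) - 1L))
  rownames(loci) <- NULL
  class(loci) <- c("gene_loci", "data.frame")
  loci
}

#' Windowed co-regulated region detection
#'
#' For each scaffold and hard cluster, emits every maximal set of member
#' genes such that the set spans at most `window` consecutive genes
#' (rank span `<= window - 1`), successive members are at most `max_gap`
#' ranks apart, and the set has at least `min_members` genes. Defaults
#' are the screen's rule: three or more members of an expression cluster
#' within a window of nine neighboring genes with a maximal distance of
#' five genes. Output order is deterministic: scaffold, first member
#' rank, cluster.
#'
#' @param loci a [order_genes()] result (or a loci data.frame, ordered
#'   internally)
#' @param assignment data.frame with `gene_id` and `cluster` columns
#'   (e.g. from [assign_clusters()]); every assigned gene needs a locus
#' @param window window size in genes, default 9
#' @param min_members minimum member genes per region, default 3
#' @param max_gap maximum rank distance between successive members,
#'   default 5
#' @param exclude_clusters cluster labels never scanned (e.g. a
#'   background label), default none
#' @return data.frame of class `"region_calls"`: `scaffold`, `cluster`,
#'   `kind` (`"windowed"`), `n_members`, `first_rank`, `last_rank`,
#'   `start_bp`, `end_bp`, `gene_ids` (comma-separated)
#' @export
find_coregulated_regions <- function(loci, assignment, window = 9L,
                                     min_members = 3L, max_gap = 5L,
                                     exclude_clusters = integer(0)) {
  if (window < min_members)
    stop("window must be at least min_members")
  loci <- ensure_ordered(loci)
  amap <- scan_cluster_map(loci, assignment)
  out <- list()
  for (sc in unique(loci$scaffold)) {
    sub <- loci[loci$scaffold == sc, , drop = FALSE]
    cl <- amap[sub$gene_id]
    for (k in sort(unique(cl[!is.na(cl) & !(cl %in% exclude_clusters)]))) {
      r <- sub$rank[!is.na(cl) & cl == k]
      if (length(r) < min_members) next
      r <- sort(r)
      sets <- maximal_windowed_sets(r, window, max_gap)
      for (s in sets) {
        if (length(s) < min_members) next
        members <- sub$gene_id[match(s, sub$rank)]
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc, cluster = k, kind = "windowed",
          n_members = length(s), first_rank = s[1L],
          last_rank = s[length(s)],
          start_bp = min(sub$start[match(s, sub$rank)]),
          end_bp = max(sub$end[match(s, sub$rank)]),
          gene_ids = paste(members, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  finalize_regions(out)
}

# Maximal member sets with rank span <= window-1 and successive gaps
# <= max_gap: greedy growth from each member. The grown endpoint is
# non-decreasing in the start index, so a set is a subset of an earlier
# one exactly when it reaches the same endpoint; keeping the first start
# per distinct endpoint yields the maximal sets.
maximal_windowed_sets <- function(r, window, max_gap) {
  n <- length(r)
  ends <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    while (j < n && r[j + 1L] - r[j] <= max_gap &&
             r[j + 1L] - r[i] <= window - 1L) j <- j + 1L
    ends[i] <- j
  }
  keep <- which(c(TRUE, diff(ends) > 0L))
  lapply(keep, function(i) r[i:ends[i]])
}

#' Adjacent same-cluster patch detection
#'
#' Maximal runs of rank-consecutive genes sharing a hard cluster, of
#' length at least `min_run` (default 3): the screen's "patches of three
#' or more genes located next to each other".
#'
#' @inheritParams find_coregulated_regions
#' @param min_run minimum run length, default 3
#' @return data.frame of class `"region_calls"` with `kind`
#'   `"adjacent_patch"`
#' @export
find_adjacent_patches <- function(loci, assignment, min_run = 3L,
                                  exclude_clusters = integer(0)) {
  loci <- ensure_ordered(loci)
  amap <- scan_cluster_map(loci, assignment)
  out <- list()
  for (sc in unique(loci$scaffold)) {
    sub <- loci[loci$scaffold == sc, , drop = FALSE]
    cl <- amap[sub$gene_id]
    key <- ifelse(is.na(cl) | cl %in% exclude_clusters, NA_integer_, cl)
    runs <- rle(paste0("k", key))
    stop_at <- cumsum(runs$lengths)
    start_at <- stop_at - runs$lengths + 1L
    for (i in seq_along(runs$lengths)) {
      if (runs$lengths[i] < min_run) next
      idx <- start_at[i]:stop_at[i]
      k <- key[idx[1L]]
      if (is.na(k)) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, cluster = k, kind = "adjacent_patch",
        n_members = length(idx), first_rank = sub$rank[idx[1L]],
        last_rank = sub$rank[idx[length(idx)]],
        start_bp = min(sub$start[idx]), end_bp = max(sub$end[idx]),
        gene_ids = paste(sub$gene_id[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  finalize_regions(out)
}

#' Neighborhood annotation of candidate genes
#'
#' For each candidate gene, reports the functional roles of genes within
#' `flank` ranks on the same scaffold and whether the candidate lies
#' inside or adjacent to a detected co-regulated region (the
#' regulator-next-to-CAZy/transporter narrative of locus figures).
#'
#' @param loci a [order_genes()] result
#' @param regions a `region_calls` data.frame (windowed and/or patches),
#'   may be empty
#' @param candidate_ids character vector of candidate genes
#' @param roles named character vector gene_id -> role (`"CAZy"`,
#'   `"transporter"`, `"regulator"`, `"other"`)
#' @param flank rank distance considered neighboring, default 1
#' @return list: `neighbors` (data.frame `candidate`, `neighbor`, `role`,
#'   `distance`), `candidates` (data.frame `gene_id`, `in_region`,
#'   `adjacent_to_region`, `near_cazy_or_transporter`)
#' @export
annotate_neighbors <- function(loci, regions, candidate_ids, roles,
                               flank = 1L) {
  loci <- ensure_ordered(loci)
  miss <- setdiff(candidate_ids, loci$gene_id)
  if (length(miss))
    stop("candidates without loci: ", paste(miss, collapse = ", "))
  region_genes <- character(0)
  region_spans <- NULL
  if (!is.null(regions) && nrow(regions) > 0L) {
    region_genes <- unique(unlist(strsplit(regions$gene_ids, ",", fixed = TRUE)))
    region_spans <- regions[, c("scaffold", "first_rank", "last_rank")]
  }
  nb <- list()
  cand <- list()
  for (g in candidate_ids) {
    row <- loci[loci$gene_id == g, ]
    sub <- loci[loci$scaffold == row$scaffold, , drop = FALSE]
    near <- sub[abs(sub$rank - row$rank) <= flank & sub$gene_id != g, ,
                drop = FALSE]
    if (nrow(near))
      nb[[length(nb) + 1L]] <- data.frame(
        candidate = g, neighbor = near$gene_id,
        role = unname(roles[near$gene_id]),
        distance = abs(near$rank - row$rank),
        stringsAsFactors = FALSE)
    adjacent <- FALSE
    if (!is.null(region_spans)) {
      rs <- region_spans[region_spans$scaffold == row$scaffold, , drop = FALSE]
      adjacent <- any(row$rank >= rs$first_rank - flank &
                        row$rank <= rs$last_rank + flank)
    }
    cand[[length(cand) + 1L]] <- data.frame(
      gene_id = g,
      in_region = g %in% region_genes,
      adjacent_to_region = adjacent,
      near_cazy_or_transporter =
        nrow(near) > 0L && any(roles[near$gene_id] %in%
                                 c("CAZy", "transporter"), na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  list(neighbors = if (length(nb)) do.call(rbind, nb) else
         data.frame(candidate = character(0), neighbor = character(0),
                    role = character(0), distance = integer(0)),
       candidates = do.call(rbind, cand))
}

#' Export region calls as BED6+
#'
#' Writes regions in BED convention (0-based half-open) with
#' `name = cluster:kind`, `score = member count` and strand `"."`.
#'
#' @param regions a `region_calls` data.frame
#' @param path output file
#' @return invisibly, the path
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$scaffold,
                    start = regions$start_bp - 1L,  # to 0-based half-open
                    end = regions$end_bp,
                    name = sprintf("cluster%d:%s", regions$cluster,
                                   regions$kind),
                    score = regions$n_members,
                    strand = ".",
                    gene_ids = regions$gene_ids,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ensure_ordered <- function(loci) {
  if (inherits(loci, "gene_loci") && "rank" %in% names(loci)) return(loci)
  order_genes(loci)
}

scan_cluster_map <- function(loci, assignment) {
  stopifnot(all(c("gene_id", "cluster") %in% names(assignment)))
  miss <- setdiff(assignment$gene_id, loci$gene_id)
  if (length(miss))
    stop("assigned genes without loci: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  amap <- assignment$cluster
  names(amap) <- assignment$gene_id
  amap
}

finalize_regions <- function(rows) {
  if (length(rows) == 0L) {
    out <- data.frame(scaffold = character(0), cluster = integer(0),
                      kind = character(0), n_members = integer(0),
                      first_rank = integer(0), last_rank = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      gene_ids = character(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$scaffold, out$first_rank, out$cluster), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("region_calls", "data.frame")
  out
}
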