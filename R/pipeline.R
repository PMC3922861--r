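# End-to-end orchestration: synthetic data (or files on disk) through
# differential calling, clustering, enrichment, genome scan, correlation
# screen and candidate selection, with every artifact written to an
# output directory.

#' Pipeline configuration
#'
#' Collects every stage parameter. Unknown keys are rejected. The
#' defaults are the screen's rule set: P < 0.01 and |log2FC| > 0.4 for
#' differential calls, a 9-gene window with >= 3 members at most 5 genes
#' apart (patches of >= 3 adjacent genes), |r| >= 0.5 for the
#' production-rate correlation, induction on >= 3 substrates, and >= 3
#' of 5 criteria with a regulatory-class gate for candidate selection.
#' The cluster count `c` and fuzzifier `m` are analysis choices, not
#' rule constants.
#'
#' @param sim a [sim_config()]; its `rng_seed` is overridden by `seed`
#' @param out_dir output directory
#' @param seed master seed for the run (simulation noise and clustering
#'   initialization are derived from it)
#' @param p_cut,lfc_cut differential-call cutoffs
#' @param n_clusters_fcm,fuzzifier,alpha,restarts fuzzy c-means settings
#'   (cluster count, fuzzifier m, core-membership threshold, restarts)
#' @param ref_fraction cumulative reference fraction defining the
#'   flagged clusters
#' @param window,min_members,max_gap windowed-region rule
#' @param min_run adjacency rule
#' @param flank neighborhood rank distance
#' @param corr_threshold,corr_method correlation screen settings
#' @param breadth_min substrates required for the induction criterion
#' @param min_criteria,require_regulatory_class,weights candidate screen
#' @param regulatory_classes class labels counted as regulatory domains
#' @param ... rejected; catches misspelled keys
#' @return validated list of class `"pipeline_config"`
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = tempfile("cazyscreen_run_"),
                            seed = 1L,
                            p_cut = 0.01, lfc_cut = 0.4,
                            n_clusters_fcm = 8L, fuzzifier = 1.25,
                            alpha = 0.5, restarts = 3L,
                            ref_fraction = 0.9,
                            window = 9L, min_members = 3L, max_gap = 5L,
                            min_run = 3L, flank = 1L,
                            corr_threshold = 0.5, corr_method = "pearson",
                            breadth_min = 3L,
                            min_criteria = 3L,
                            require_regulatory_class = TRUE,
                            weights = rep(1, 5),
                            regulatory_classes = "fungal_C6_TF",
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown pipeline_config keys: ",
         paste(names(extra), collapse = ", "))
  stopifnot(inherits(sim, "sim_config"))
  sim$rng_seed <- as.integer(seed)
  cfg <- list(sim = sim, out_dir = out_dir, seed = as.integer(seed),
              p_cut = p_cut, lfc_cut = lfc_cut,
              n_clusters_fcm = as.integer(n_clusters_fcm),
              fuzzifier = fuzzifier, alpha = alpha,
              restarts = as.integer(restarts),
              ref_fraction = ref_fraction,
              window = as.integer(window),
              min_members = as.integer(min_members),
              max_gap = as.integer(max_gap),
              min_run = as.integer(min_run), flank = as.integer(flank),
              corr_threshold = corr_threshold, corr_method = corr_method,
              breadth_min = as.integer(breadth_min),
              min_criteria = as.integer(min_criteria),
              require_regulatory_class = require_regulatory_class,
              weights = weights,
              regulatory_classes = regulatory_classes)
  if (cfg$p_cut <= 0 || cfg$lfc_cut <= 0)
    stop("p_cut and lfc_cut must be positive")
  if (cfg$window < cfg$min_members) stop("window must be >= min_members")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full candidate-regulator screen
#'
#' Simulates (or accepts) an induction dataset and runs every stage,
#' writing all artifacts plus a JSON run log into `config$out_dir`.
#' Given identical config and seed the output tree is byte-identical,
#' and every output file re-parses through the package's own readers.
#'
#' @param config a [pipeline_config()]
#' @param dataset optionally, a precomputed `synthetic_dataset` (the
#'   simulate stage is then skipped); defaults to simulating from
#'   `config$sim`
#' @return invisibly, a list with every stage result: `dataset`,
#'   `contrasts`, `breadth`, `model`, `assignment`, `reference`,
#'   `enrichment`, `regions`, `patches`, `neighbors`, `correlation`,
#'   `evidence`, `report`, `log`
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  version <- as.character(utils::packageVersion("cazyscreen"))
  meta <- list(package = "cazyscreen", version = version,
               seed = config$seed,
               config_hash = object_hash(config[setdiff(names(config),
                                                        "out_dir")]))

  ds <- tryCatch({
    if (is.null(dataset)) simulate_experiment(config$sim) else dataset
  }, error = function(e) stage_stop("simulate", conditionMessage(e)))
  write_synthetic_inputs(ds, file.path(config$out_dir, "inputs"))

  contrasts <- tryCatch({
    tbl <- fit_contrasts(ds$expression)
    call_differential(tbl, p_cut = config$p_cut, lfc_cut = config$lfc_cut)
  }, error = function(e) stage_stop("diffexpr", conditionMessage(e)))
  breadth <- induction_breadth(contrasts)
  write_contrasts_tsv(contrasts, file.path(config$out_dir, "contrasts.tsv"),
                      meta)

  clust <- tryCatch({
    prof <- standardize_profiles(profile_matrix(contrasts))
    model <- fuzzy_cmeans(prof, c = config$n_clusters_fcm,
                          m = config$fuzzifier,
                          seed = config$seed + 1000L,
                          n_restarts = config$restarts)
    assignment <- assign_clusters(model, alpha = config$alpha)
    list(profiles = prof, model = model, assignment = assignment)
  }, error = function(e) stage_stop("cluster", conditionMessage(e)))
  write_clusters_tsv(clust$assignment,
                     file.path(config$out_dir, "clusters.tsv"), meta)
  write_tsv(data.frame(cluster = rownames(clust$model$centroids),
                       clust$model$centroids, check.names = FALSE),
            file.path(config$out_dir, "centroids.tsv"), meta)

  ref <- tryCatch({
    refs <- intersect(ds$reference_genes, clust$assignment$gene_id)
    if (length(refs) == 0L) stop("no reference gene survived clustering")
    reference_clusters(clust$assignment, refs,
                       min_fraction = config$ref_fraction)
  }, error = function(e) stage_stop("reference_clusters",
                                    conditionMessage(e)))

  enr <- tryCatch({
    universe <- clust$assignment$gene_id
    in_flagged <- clust$assignment$gene_id[
      clust$assignment$cluster %in% ref$clusters]
    class_enrichment_all(in_flagged, ds$annotations, universe)
  }, error = function(e) stage_stop("enrichment", conditionMessage(e)))
  write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"), meta)

  scan <- tryCatch({
    loci <- order_genes(ds$loci)
    regions <- find_coregulated_regions(loci, clust$assignment,
                                        window = config$window,
                                        min_members = config$min_members,
                                        max_gap = config$max_gap)
    patches <- find_adjacent_patches(loci, clust$assignment,
                                     min_run = config$min_run)
    list(loci = loci, regions = regions, patches = patches)
  }, error = function(e) stage_stop("genome_scan", conditionMessage(e)))
  all_regions <- rbind(as.data.frame(scan$regions),
                       as.data.frame(scan$patches))
  write_tsv(all_regions, file.path(config$out_dir, "regions.tsv"), meta)
  if (nrow(all_regions))
    write_regions_bed(all_regions, file.path(config$out_dir, "regions.bed"))

  roles <- annotation_roles(ds$annotations, config$regulatory_classes)
  regulatory_ids <- unique(
    ds$annotations$gene_id[ds$annotations$class_label %in%
                             config$regulatory_classes])
  nbr <- tryCatch({
    annotate_neighbors(scan$loci, scan$regions, regulatory_ids, roles,
                       flank = config$flank)
  }, error = function(e) stage_stop("neighbors", conditionMessage(e)))

  corr <- tryCatch({
    production_correlation(ds$chemostat$rates, ds$chemostat$expression,
                           threshold = config$corr_threshold,
                           method = config$corr_method)
  }, error = function(e) stage_stop("correlate", conditionMessage(e)))
  write_tsv(as.data.frame(corr),
            file.path(config$out_dir, "correlations.tsv"), meta)

  screen <- tryCatch({
    universe <- ds$expression$gene_ids
    region_genes <- unique(unlist(strsplit(all_regions$gene_ids, ",",
                                           fixed = TRUE)))
    near_ids <- nbr$candidates$gene_id[nbr$candidates$near_cazy_or_transporter]
    ev <- build_evidence(universe = universe, breadth = breadth,
                         co_clustered = ref$co_clustered,
                         correlation = corr,
                         region_gene_ids = region_genes,
                         near_ids = near_ids,
                         regulatory_class_ids = regulatory_ids,
                         proteome_flags = ds$truth$proteome_flags,
                         breadth_min = config$breadth_min)
    rep <- select_candidates(ev, min_criteria = config$min_criteria,
                             require_regulatory_class =
                               config$require_regulatory_class,
                             weights = config$weights)
    list(evidence = ev, report = rep)
  }, error = function(e) stage_stop("screen", conditionMessage(e)))
  write_tsv(as.data.frame(screen$evidence),
            file.path(config$out_dir, "evidence.tsv"), meta)
  write_tsv(as.data.frame(screen$report),
            file.path(config$out_dir, "candidates.tsv"), meta)

  # fold-change heatmap matrix for the reference and regulatory genes
  hm_genes <- unique(c(ds$reference_genes, regulatory_ids))
  hm <- profile_matrix(contrasts)
  hm <- hm[rownames(hm) %in% hm_genes, , drop = FALSE]
  write_expression_tsv(hm, file.path(config$out_dir,
                                     "foldchange_matrix.tsv"), meta)

  smry <- attr(contrasts, "summary")
  log <- list(
    package = "cazyscreen", version = version, seed = config$seed,
    config_hash = meta$config_hash,
    parameters = list(p_cut = config$p_cut, lfc_cut = config$lfc_cut,
                      window = config$window,
                      min_members = config$min_members,
                      max_gap = config$max_gap, min_run = config$min_run,
                      corr_threshold = config$corr_threshold,
                      breadth_min = config$breadth_min,
                      n_clusters_fcm = config$n_clusters_fcm,
                      fuzzifier = config$fuzzifier, alpha = config$alpha,
                      min_criteria = config$min_criteria),
    contrast_summary = smry,
    n_co_clustered = length(ref$co_clustered),
    flagged_clusters = ref$clusters,
    n_regions = nrow(scan$regions),
    n_patches = nrow(scan$patches),
    top_enrichment = enr[1, , drop = FALSE],
    n_selected = sum(screen$report$selected))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")

  invisible(list(dataset = ds, contrasts = contrasts, breadth = breadth,
                 model = clust$model, assignment = clust$assignment,
                 reference = ref, enrichment = enr,
                 regions = scan$regions, patches = scan$patches,
                 neighbors = nbr, correlation = corr,
                 evidence = screen$evidence, report = screen$report,
                 log = log))
}

#' Derive gene roles from annotation classes
#'
#' Maps each annotated gene to one of `"CAZy"`, `"transporter"`,
#' `"regulator"` or `"other"`, with CAZy taking precedence.
#'
#' @param annotations long annotation data.frame (`gene_id`,
#'   `class_label`)
#' @param regulatory_classes class labels treated as regulators
#' @return named character vector of roles, one entry per annotated gene
#' @export
annotation_roles <- function(annotations, regulatory_classes) {
  genes <- unique(annotations$gene_id)
  roles <- stats::setNames(rep("other", length(genes)), genes)
  pick <- function(class) unique(annotations$gene_id[
    annotations$class_label %in% class])
  roles[pick("sugar_transporter")] <- "transporter"
  roles[pick(regulatory_classes)] <- "regulator"
  roles[pick("CAZy_enzyme")] <- "CAZy"
  roles
}
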