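# Differential-induction calls: induced vs. uninduced control at each
# substrate and time point, with an empirical-Bayes moderated t statistic
# and the cutoffs P < 0.01 and |log2 fold change| > 0.4.

#' Construct an expression dataset
#'
#' Bundles a log2 signal matrix with its sample design and validates the
#' two against each other.
#'
#' @param matrix numeric gene x sample matrix of log2 signals, with gene
#'   ids as rownames and sample ids as colnames; no missing values
#' @param design data.frame with columns `sample_id`, `substrate`,
#'   `time_h`, `replicate`, `role` (`"induced"` or `"control"`)
#' @return list of class `"expression_dataset"` with elements `matrix`,
#'   `design`, `gene_ids`
#' @export
expression_dataset <- function(matrix, design) {
  stopifnot(is.matrix(matrix), is.numeric(matrix), is.data.frame(design))
  need <- c("sample_id", "substrate", "time_h", "replicate", "role")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (!all(design$role %in% c("induced", "control")))
    stop("design$role must be 'induced' or 'control'")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene rownames and sample colnames")
  extra <- setdiff(colnames(matrix), design$sample_id)
  if (length(extra))
    stop("samples absent from design: ", paste(extra, collapse = ", "))
  extra2 <- setdiff(design$sample_id, colnames(matrix))
  if (length(extra2))
    stop("design samples absent from matrix: ", paste(extra2, collapse = ", "))
  if (anyNA(matrix)) {
    idx <- which(is.na(matrix), arr.ind = TRUE)[1, ]
    stop(sprintf("missing expression value at gene '%s', sample '%s'",
                 rownames(matrix)[idx[1]], colnames(matrix)[idx[2]]))
  }
  design <- design[match(colnames(matrix), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(matrix = matrix, design = design,
                 gene_ids = rownames(matrix)),
            class = "expression_dataset")
}

#' Fit induced-vs-control contrasts with a moderated t statistic
#'
#' For every (substrate, time) cell, induced samples are compared to the
#' control samples at the same time point as an independent two-group
#' comparison: `log2fc` is the difference of group means and `s2` the
#' pooled residual variance with `d = n_i + n_c - 2` degrees of freedom.
#' A single global prior `(d0, s0^2)` is estimated across all gene x
#' contrast variances by moment matching on `log(s2)` (scaled-F model of
#' gene-wise variances), the posterior variance is
#' `s~^2 = (d0 s0^2 + d s2) / (d0 + d)`, and
#' `t = log2fc / (s~ sqrt(1/n_i + 1/n_c))` is referred to a t
#' distribution on `d0 + d` degrees of freedom (two-sided). When the
#' moment estimator diverges (`d0 = Inf`, i.e. the variances are
#' homogeneous) the statistic reduces to a z-like statistic against the
#' common variance; this fallback is by design, not an error.
#'
#' Cells with fewer than two replicates on either side are kept in the
#' table with `NA` statistics and `available = FALSE`, never silently
#' treated as null.
#'
#' @param data an [expression_dataset()]
#' @param prior_df override the estimated prior degrees of freedom `d0`;
#'   `0` gives the ordinary pooled two-sample t, `Inf` the shrinkage
#'   limit. Default `NULL` estimates `d0` from the data.
#' @param s2_floor variances of exactly zero are replaced by the smallest
#'   positive `s2` observed so the log-moment estimator stays finite
#'   (`TRUE` by default)
#' @return data.frame of class `"contrast_table"` with one row per gene
#'   and contrast: `gene_id`, `substrate`, `time_h`, `log2fc`, `s2`,
#'   `df`, `t`, `p`, `p_adj` (Benjamini-Hochberg within contrast,
#'   informational), `call` (0 until [call_differential()] is applied),
#'   `available`; the prior is attached as attributes `d0`, `s0_sq`
#' @export
fit_contrasts <- function(data, prior_df = NULL, s2_floor = TRUE) {
  stopifnot(inherits(data, "expression_dataset"))
  des <- data$design
  X <- data$matrix
  cells <- unique(des[des$role == "induced", c("substrate", "time_h")])
  cells <- cells[order(cells$substrate, cells$time_h), , drop = FALSE]
  if (nrow(cells) == 0L) stop("no induced samples in design")

  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    s <- cells$substrate[i]; t <- cells$time_h[i]
    ind <- des$sample_id[des$role == "induced" & des$substrate == s &
                           des$time_h == t]
    ctl <- des$sample_id[des$role == "control" & des$time_h == t]
    ni <- length(ind); nc <- length(ctl)
    if (ni < 2L || nc < 2L) {
      res[[i]] <- data.frame(gene_id = rownames(X), substrate = s, time_h = t,
                             log2fc = NA_real_, s2 = NA_real_, df = NA_real_,
                             n_i = ni, n_c = nc, available = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    xi <- X[, ind, drop = FALSE]
    xc <- X[, ctl, drop = FALSE]
    mi <- rowMeans(xi)
    mc <- rowMeans(xc)
    ssi <- rowSums((xi - mi)^2)
    ssc <- rowSums((xc - mc)^2)
    d <- ni + nc - 2L
    res[[i]] <- data.frame(gene_id = rownames(X), substrate = s, time_h = t,
                           log2fc = mi - mc, s2 = (ssi + ssc) / d,
                           df = as.numeric(d), n_i = ni, n_c = nc,
                           available = TRUE, stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, res)
  rownames(tbl) <- NULL

  ok <- tbl$available
  s2 <- tbl$s2[ok]
  if (s2_floor && any(s2 <= 0)) {
    floor_val <- min(s2[s2 > 0])
    if (!is.finite(floor_val))
      stop("all residual variances are zero; cannot moderate")
    s2[s2 <= 0] <- floor_val
    tbl$s2[ok] <- s2
  }
  prior <- if (is.null(prior_df)) {
    fit_variance_prior(s2, tbl$df[ok])
  } else {
    list(d0 = prior_df, s0_sq = if (is.finite(prior_df) && prior_df > 0)
      fit_variance_prior(s2, tbl$df[ok])$s0_sq else mean(s2))
  }

  d0 <- prior$d0; s0 <- prior$s0_sq
  d <- tbl$df[ok]
  post_s2 <- if (is.finite(d0)) (d0 * s0 + d * s2) / (d0 + d) else rep(s0, length(s2))
  se <- sqrt(post_s2 * (1 / tbl$n_i[ok] + 1 / tbl$n_c[ok]))
  tval <- tbl$log2fc[ok] / se
  df_total <- if (is.finite(d0)) d0 + d else Inf
  pval <- 2 * pt(-abs(tval), df = df_total)

  tbl$t <- NA_real_; tbl$p <- NA_real_
  tbl$t[ok] <- tval
  tbl$p[ok] <- pval
  tbl$p_adj <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- tbl$substrate == cells$substrate[i] & tbl$time_h == cells$time_h[i] &
      tbl$available
    tbl$p_adj[sel] <- p.adjust(tbl$p[sel], method = "BH")
  }
  tbl$call <- ifelse(tbl$available, 0L, NA_integer_)
  attr(tbl, "d0") <- d0
  attr(tbl, "s0_sq") <- s0
  class(tbl) <- c("contrast_table", "data.frame")
  tbl
}

# Moment matching of the scaled-F model for gene-wise variances on the
# log scale: E[log s2] and Var[log s2] determine (d0, s0^2) through the
# digamma/trigamma functions. Diverging trigamma inversion (observed
# variance of log s2 not exceeding its sampling component) yields
# d0 = Inf.
fit_variance_prior <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Apply the significance and fold-change cutoffs
#'
#' Populates the call column of a contrast table: `+1` (induction) when
#' `p < p_cut` and `log2fc > lfc_cut`, `-1` (repression) when `p < p_cut`
#' and `log2fc < -lfc_cut`, else `0`. Defaults are the screen's cutoffs,
#' P < 0.01 on the unadjusted p-value and 0.4 on the log2 fold change.
#'
#' @param table a `contrast_table` from [fit_contrasts()]
#' @param p_cut p-value cutoff (exclusive), default 0.01
#' @param lfc_cut absolute log2 fold-change cutoff (exclusive), default 0.4
#' @param use_adjusted call on the Benjamini-Hochberg adjusted p instead
#'   of the raw p (off by default; the raw-p rule is the screen's)
#' @return the table with `call` populated; a per-contrast summary of
#'   up/down counts is attached as attribute `"summary"`
#' @export
call_differential <- function(table, p_cut = 0.01, lfc_cut = 0.4,
                              use_adjusted = FALSE) {
  stopifnot(inherits(table, "contrast_table"))
  if (!is.numeric(p_cut) || p_cut <= 0 || !is.numeric(lfc_cut) || lfc_cut <= 0)
    stop("p_cut and lfc_cut must be positive")
  p <- if (use_adjusted) table$p_adj else table$p
  up <- table$available & p < p_cut & table$log2fc > lfc_cut
  dn <- table$available & p < p_cut & table$log2fc < -lfc_cut
  table$call <- ifelse(table$available, 0L, NA_integer_)
  table$call[up] <- 1L
  table$call[dn] <- -1L
  cells <- unique(table[, c("substrate", "time_h")])
  smry <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$substrate == cells$substrate[i] &
      table$time_h == cells$time_h[i]
    data.frame(substrate = cells$substrate[i], time_h = cells$time_h[i],
               n_up = sum(table$call[sel] == 1L, na.rm = TRUE),
               n_down = sum(table$call[sel] == -1L, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  attr(table, "summary") <- smry
  attr(table, "p_cut") <- p_cut
  attr(table, "lfc_cut") <- lfc_cut
  table
}

#' Count inducing substrates per gene
#'
#' Number of distinct substrates on which a gene is called induced
#' (`call = +1`) at one or more time points. The candidate screen uses
#' breadth >= 3 ("induction by three or more of the cellulase- or
#' hemicellulase-inducing substrates").
#'
#' @param table a called `contrast_table`
#' @return named integer vector, one entry per gene
#' @export
induction_breadth <- function(table) {
  stopifnot(inherits(table, "contrast_table"))
  up <- table[!is.na(table$call) & table$call == 1L, c("gene_id", "substrate")]
  genes <- unique(table$gene_id)
  out <- integer(length(genes))
  names(out) <- genes
  if (nrow(up)) {
    cnt <- tapply(up$substrate, up$gene_id, function(s) length(unique(s)))
    out[names(cnt)] <- as.integer(cnt)
  }
  out
}

#' Per-gene fold-change profile matrix
#'
#' Reshapes a contrast table into a gene x (substrate, time) matrix of
#' log2 fold changes, the representation handed to the clustering stage
#' (and the matrix behind fold-change heatmaps).
#'
#' @param table a `contrast_table`
#' @param value column to spread, default `"log2fc"`
#' @return numeric matrix, columns named `substrate_t<time>`
#' @export
profile_matrix <- function(table, value = "log2fc") {
  stopifnot(inherits(table, "contrast_table"), value %in% names(table))
  avail <- table[table$available, , drop = FALSE]
  cols <- unique(avail[, c("substrate", "time_h")])
  cols <- cols[order(cols$substrate, cols$time_h), , drop = FALSE]
  genes <- unique(table$gene_id)
  m <- matrix(NA_real_, length(genes), nrow(cols),
              dimnames = list(genes, sprintf("%s_t%g", cols$substrate,
                                             cols$time_h)))
  for (i in seq_len(nrow(cols))) {
    sel <- avail$substrate == cols$substrate[i] &
      avail$time_h == cols$time_h[i]
    m[avail$gene_id[sel], i] <- avail[[value]][sel]
  }
  m
}
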