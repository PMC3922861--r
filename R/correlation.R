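# Screen of gene expression against the specific protein production
# rate across chemostat conditions.

#' Production-rate correlation screen
#'
#' Correlates each gene's expression across chemostat conditions with
#' the per-condition specific protein production rate and flags genes
#' whose absolute correlation reaches the threshold (default 0.5, the
#' screen's cutoff). Pearson correlation is the default; Spearman is
#' available.
#'
#' @param rates named numeric vector of specific protein production
#'   rates, one per condition; >= 3 conditions, not all equal
#' @param expression gene x condition matrix with matching condition
#'   columns
#' @param threshold absolute correlation required to pass, default 0.5
#' @param method `"pearson"` (default) or `"spearman"`
#' @return data.frame of class `"correlation_screen"`: `gene_id`, `r`,
#'   `pass`, `sign` (-1/0/+1; 0 when undefined). Genes with zero
#'   expression variance get `r = NA` and never pass.
#' @export
production_correlation <- function(rates, expression, threshold = 0.5,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(rates) < 3L)
    stop("correlation screening needs >= 3 conditions")
  if (length(unique(rates)) < 2L)
    stop("rates must not all be equal")
  stopifnot(is.matrix(expression))
  if (!is.null(names(rates))) {
    if (is.null(colnames(expression)))
      colnames(expression) <- names(rates)
    miss <- setdiff(names(rates), colnames(expression))
    if (length(miss))
      stop("conditions without expression: ", paste(miss, collapse = ", "))
    expression <- expression[, names(rates), drop = FALSE]
  }
  if (ncol(expression) != length(rates))
    stop("expression columns must match conditions")
  r <- suppressWarnings(as.numeric(cor(t(expression), rates, method = method)))
  r[!is.finite(r)] <- NA_real_
  pass <- !is.na(r) & abs(r) >= threshold
  out <- data.frame(gene_id = rownames(expression), r = r, pass = pass,
                    sign = ifelse(is.na(r), 0L, as.integer(sign(r))),
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_screen", "data.frame")
  out
}
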