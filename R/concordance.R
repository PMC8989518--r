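#' Fold-change concordance between two differential tables
#'
#' Intersects two differential tables by gene id, keeps genes significant
#' at `p_thresh` in both tables (`mode = "both"`, the default) or in at
#' least one (`mode = "either"`), and reports the Pearson correlation of
#' the log2 fold changes together with the ordinary least-squares
#' regression of table `b`'s log2FC on table `a`'s.
#'
#' @param a,b `data.frame`s with columns `gene_id`, `log2fc`, `p_value`;
#'   gene ids unique within each table.
#' @param p_thresh Significance cutoff applied per table (default 0.05,
#'   strict).
#' @param mode `"both"` or `"either"`.
#' @return List with `n_genes`, `pearson_r`, `r_squared`, `slope`,
#'   `intercept`, `p_correlation`.
#' @export
fc_concordance <- function(a, b, p_thresh = 0.05,
                           mode = c("both", "either")) {
  mode <- match.arg(mode)
  for (tab in list(a, b)) {
    miss <- setdiff(c("gene_id", "log2fc", "p_value"), names(tab))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$gene_id)) stop("duplicate gene ids in FC table")
  }
  m <- merge(a, b, by = "gene_id", suffixes = c("_a", "_b"))
  keep <- if (mode == "both") {
    m$p_value_a < p_thresh & m$p_value_b < p_thresh
  } else {
    m$p_value_a < p_thresh | m$p_value_b < p_thresh
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L)
    stop("only ", nrow(m), " genes survive intersection and filtering; ",
         "at least 3 required")
  ct <- stats::cor.test(m$log2fc_a, m$log2fc_b, method = "pearson")
  fit <- stats::lm(log2fc_b ~ log2fc_a, data = m)
  r <- unname(ct$estimate)
  list(
    n_genes = nrow(m),
    pearson_r = r,
    r_squared = r^2,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    p_correlation = ct$p.value
  )
}
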