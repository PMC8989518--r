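#' Log2 fold change and Student's t-test on LFQ intensities
#'
#' Intensities of 0 are treated as missing (the usual label-free
#' quantification convention); remaining values are log2-transformed.
#' `log2FC = mean(log2 bait) - mean(log2 control)`. The p-value comes from
#' a two-sided, two-sample, pooled-variance Student's t-test on the log2
#' values. Degenerate cases follow fixed conventions: if the pooled
#' variance is 0 the p-value is 0 when the means differ and 1 when they do
#' not; if either group has fewer than 2 non-missing values the p-value is
#' undefined (`NA`).
#'
#' @param bait,control Numeric vectors of non-negative raw intensities.
#' @return List with `log2fc` and `p_value`.
#' @export
log2fc_and_ttest <- function(bait, control) {
  if (any(bait < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE))
    stop("negative intensity")
  b <- log2(bait[!is.na(bait) & bait > 0])
  c_ <- log2(control[!is.na(control) & control > 0])
  log2fc <- if (length(b) && length(c_)) mean(b) - mean(c_) else NA_real_
  if (length(b) < 2L || length(c_) < 2L)
    return(list(log2fc = log2fc, p_value = NA_real_))
  n1 <- length(b); n2 <- length(c_)
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * stats::var(b) + (n2 - 1L) * stats::var(c_)) / df
  if (s2 == 0) {
    p <- if (mean(b) == mean(c_)) 1 else 0
  } else {
    tstat <- (mean(b) - mean(c_)) / sqrt(s2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df = df)
  }
  list(log2fc = log2fc, p_value = p)
}

#' Shortlist proximity-labelling interactors
#'
#' Applies the four conjunctive filters used to call high-confidence BioID
#' interactors, all strict: razor + unique peptides `> 4`, sequence
#' coverage `> 20` percent, Student's t-test p-value `< 0.05` versus the
#' free-ligase control, and `log2` fold change `> 1`. An undefined p-value
#' (too few quantified replicates) fails the p filter. No multiple-testing
#' correction is applied.
#'
#' @param quant `data.frame` with columns `protein_id`,
#'   `razor_unique_peptides`, `coverage_pct`, then per-replicate intensity
#'   columns named in `bait_cols` / `control_cols`.
#' @param bait_cols,control_cols Names of the bait / control intensity
#'   columns. Default: columns starting `bait_` / `control_`.
#' @param min_peptides,min_coverage,max_p,min_log2fc Filter thresholds
#'   (defaults 4, 20, 0.05, 1; all compared strictly).
#' @return `data.frame` with `protein_id`, `log2fc`, `p_value`, `passes`,
#'   and `failed_filters` (comma-separated names, empty when passing).
#' @export
shortlist <- function(quant,
                      bait_cols = grep("^bait_", names(quant), value = TRUE),
                      control_cols = grep("^control_", names(quant),
                                          value = TRUE),
                      min_peptides = 4, min_coverage = 20,
                      max_p = 0.05, min_log2fc = 1) {
  need <- c("protein_id", "razor_unique_peptides", "coverage_pct")
  miss <- setdiff(need, names(quant))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(bait_cols) == 0L || length(control_cols) == 0L)
    stop("no bait/control intensity columns found")

  res <- lapply(seq_len(nrow(quant)), function(i) {
    log2fc_and_ttest(as.numeric(quant[i, bait_cols]),
                     as.numeric(quant[i, control_cols]))
  })
  log2fc <- vapply(res, `[[`, numeric(1), "log2fc")
  p <- vapply(res, `[[`, numeric(1), "p_value")

  fail <- cbind(
    peptides = !(quant$razor_unique_peptides > min_peptides),
    coverage = !(quant$coverage_pct > min_coverage),
    p_value  = !(!is.na(p) & p < max_p),
    log2fc   = !(!is.na(log2fc) & log2fc > min_log2fc)
  )
  data.frame(
    protein_id = quant$protein_id,
    log2fc = log2fc,
    p_value = p,
    passes = rowSums(fail) == 0L,
    failed_filters = apply(fail, 1L, function(f)
      paste(colnames(fail)[f], collapse = ",")),
    stringsAsFactors = FALSE
  )
}
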