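#' Splice-event categories handled by the filters
#' @return Character vector of the five event types.
#' @export
splice_event_types <- function() c("SE", "MXE", "RI", "A3SS", "A5SS")

#' Junction-count post-filter for splice-event tables
#'
#' Keeps an event iff `FDR < 0.05` and its type-specific read-support rule
#' holds:
#' * A3SS / A5SS: at least 10 reads across all exon:exon junctions of the
#'   event, i.e. `IJC_1 + IJC_2 + SJC >= 10`;
#' * RI / SE / MXE: `SJC >= 10`, or one inclusion junction count `>= 10`
#'   and the other `>= 5`.
#'
#' All inequalities on FDR are strict (`< 0.05`); the count thresholds are
#' inclusive, as written. The filter is idempotent.
#'
#' @param events `data.frame` with columns `event_id`, `type`, `IJC_1`,
#'   `IJC_2`, `SJC`, `FDR`.
#' @param fdr_max FDR cutoff (default 0.05, strict).
#' @return The kept rows, order preserved.
#' @export
filter_splice_events <- function(events, fdr_max = 0.05) {
  need <- c("event_id", "type", "IJC_1", "IJC_2", "SJC", "FDR")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(events$type), splice_event_types())
  if (length(bad)) stop("unknown splice event type: ", bad[1L])
  if (any(events$IJC_1 < 0 | events$IJC_2 < 0 | events$SJC < 0))
    stop("negative junction count")
  if (any(events$FDR < 0 | events$FDR > 1)) stop("FDR outside [0,1]")

  alt_ss <- events$type %in% c("A3SS", "A5SS")
  support <- ifelse(
    alt_ss,
    events$IJC_1 + events$IJC_2 + events$SJC >= 10,
    events$SJC >= 10 |
      (pmax(events$IJC_1, events$IJC_2) >= 10 &
       pmin(events$IJC_1, events$IJC_2) >= 5)
  )
  events[events$FDR < fdr_max & support, , drop = FALSE]
}

#' Tally splice events per category
#'
#' @param events Splice-event `data.frame` (typically already filtered).
#' @return Named integer vector over `SE, MXE, RI, A3SS, A5SS`; sums to
#'   `nrow(events)`.
#' @export
tally_event_types <- function(events) {
  bad <- setdiff(unique(events$type), splice_event_types())
  if (length(bad)) stop("unknown splice event type: ", bad[1L])
  tab <- table(factor(events$type, levels = splice_event_types()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-event dPPAU: condition minus control mean proximal usage
#'
#' `dPPAU(event) = mean(PPAU over condition samples) - mean(PPAU over
#' control samples)`, in percentage-point units on `[-100, 100]`. Positive
#' values mean increased proximal polyA-site usage in the condition.
#'
#' @param ppau `data.frame` with `event_id`, `gene`, then one numeric PPAU
#'   column per sample (percent, 0-100).
#' @param groups Named character vector mapping each sample column to
#'   `"control"` or `"condition"`.
#' @return `data.frame` with `event_id`, `gene`, `dppau`.
#' @export
compute_dppau <- function(ppau, groups) {
  samples <- names(groups)
  miss <- setdiff(samples, names(ppau))
  if (length(miss)) stop("sample columns missing from PPAU table: ",
                         paste(miss, collapse = ", "))
  if (!all(groups %in% c("control", "condition")))
    stop("groups must be 'control' or 'condition'")
  ctrl <- samples[groups == "control"]
  cond <- samples[groups == "condition"]
  if (length(ctrl) == 0L || length(cond) == 0L)
    stop("both a control and a condition group are required")
  vals <- as.matrix(ppau[, samples, drop = FALSE])
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 100))
    stop("PPAU values must lie in [0, 100]")
  data.frame(
    event_id = ppau$event_id,
    gene = ppau$gene,
    dppau = rowMeans(vals[, cond, drop = FALSE]) -
            rowMeans(vals[, ctrl, drop = FALSE]),
    stringsAsFactors = FALSE
  )
}

#' Classify dPPAU shifts at fixed thresholds
#'
#' At each threshold `t`, counts `proximal_up = #{dPPAU > t}` and
#' `proximal_down = #{dPPAU < -t}` (strict inequalities); events with
#' `|dPPAU| <= t` are not counted. Counts are therefore non-increasing in
#' `t`.
#'
#' @param dppau `data.frame` from [compute_dppau()], or a numeric vector
#'   of dPPAU values.
#' @param thresholds Non-negative thresholds (default `c(0, 20)`).
#' @return `data.frame` with `threshold`, `proximal_up`, `proximal_down`.
#' @export
classify_dppau <- function(dppau, thresholds = c(0, 20)) {
  if (is.data.frame(dppau)) dppau <- dppau$dppau
  if (any(thresholds < 0)) stop("thresholds must be non-negative")
  data.frame(
    threshold = thresholds,
    proximal_up = vapply(thresholds, function(t) sum(dppau > t), integer(1)),
    proximal_down = vapply(thresholds, function(t) sum(dppau < -t), integer(1))
  )
}
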