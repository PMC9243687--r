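#' Near miss by units of blood transfused
#'
#' Buckets transfused women by the number of units of whole blood or
#' packed red cells received (1, 2, ..., `max_units - 1`, then a terminal
#' ">= max_units" bucket; women with 0 units are excluded) and counts, in
#' each bucket, how many are classified positive under each criteria set.
#' Under the WHO tool every woman at or above the 5-unit cut-off is a near
#' miss by definition, so the WHO column saturates in those buckets; an
#' any-volume criterion additionally sweeps up the low-unit strata.
#'
#' @param cohort an `mnm_cohort` or cohort-layout data frame.
#' @param criteria_sets list of `mnm_criteria` or set id strings.
#' @param max_units first bucket treated as terminal ">= max_units"
#'   (default 5, the WHO transfusion cut-off).
#' @return data frame with columns `units` (e.g. `"1"`, ..., `">=5"`),
#'   `n_women`, and one positive-count column per set id. Empty cohorts
#'   (or cohorts with no transfused women) give zero rows.
#' @export
transfusion_curve <- function(cohort, criteria_sets = list("who_2011", "global_network_2016"),
                              max_units = 5L) {
  if (max_units < 1) stop("max_units must be >= 1")
  cohort <- as.data.frame(cohort)
  criteria_sets <- lapply(criteria_sets, function(cs) {
    if (is.character(cs)) criteria_set(cs) else cs
  })
  transfused <- cohort[cohort$transfusion_units >= 1, , drop = FALSE]
  if (nrow(transfused) == 0) {
    out <- data.frame(units = character(), n_women = integer(), stringsAsFactors = FALSE)
    for (cs in criteria_sets) out[[cs$set_id]] <- integer()
    return(out)
  }
  bucket <- pmin(transfused$transfusion_units, max_units)
  levels_ <- seq_len(max_units)
  labels_ <- c(as.character(seq_len(max_units - 1L)), paste0(">=", max_units))
  if (max_units == 1L) labels_ <- ">=1"
  occupied <- sort(unique(bucket))
  out <- data.frame(units = labels_[occupied],
                    n_women = as.integer(table(factor(bucket, levels = levels_))[occupied]),
                    stringsAsFactors = FALSE)
  for (cs in criteria_sets) {
    res <- classify_cohort(transfused, cs)
    out[[cs$set_id]] <- vapply(occupied, function(b) sum(res$positive[bucket == b]), integer(1))
  }
  out
}

# locate the unique transfusion threshold predicate of a set
find_transfusion_predicate <- function(criteria) {
  is_tx <- vapply(criteria$predicates, function(p) {
    e <- p$expression
    !is.null(e$measurement) && e$measurement == "transfusion_units" && !is.null(e$cmp)
  }, logical(1))
  if (sum(is_tx) != 1) {
    stop("criteria configuration error: set '", criteria$set_id,
         "' must contain exactly one transfusion threshold predicate (found ",
         sum(is_tx), ")")
  }
  which(is_tx)
}

#' Sensitivity of near-miss counts to the transfusion cut-off
#'
#' Re-runs classification with the set's transfusion threshold predicate
#' replaced by ">= t units" for each candidate cut-off `t`, leaving every
#' other predicate untouched, and counts the resulting near misses
#' (positive survivors). Lowering the cut-off can only add positives, so
#' the count is non-increasing in `t`; at `t = 1` the predicate is
#' equivalent to an any-volume criterion for whole-unit records.
#'
#' @param cohort an `mnm_cohort` or cohort-layout data frame.
#' @param base_set criteria set containing exactly one transfusion
#'   threshold predicate (default WHO 2011).
#' @param thresholds integer cut-offs to evaluate.
#' @return data frame with columns `threshold` and `n_near_miss`.
#' @export
threshold_sweep <- function(cohort, base_set = criteria_set("who_2011"),
                            thresholds = 1:8) {
  if (is.character(base_set)) base_set <- criteria_set(base_set)
  idx <- find_transfusion_predicate(base_set)
  counts <- vapply(thresholds, function(t) {
    variant <- base_set
    variant$predicates[[idx]]$expression <- list(measurement = "transfusion_units",
                                                 cmp = ">=", value = t)
    res <- classify_cohort(cohort, variant)
    sum(res$verdict == "near_miss")
  }, integer(1))
  data.frame(threshold = as.integer(thresholds), n_near_miss = counts)
}
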