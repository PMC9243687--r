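#' Evaluate a predicate expression over a cohort
#'
#' The engine evaluates each expression as a logical vector over all rows
#' of a cohort-layout data frame. A missing measurement (`NA`) never
#' satisfies a threshold or range predicate: classification asserts
#' severity only from observed data.
#'
#' @param expr an expression in the criteria grammar (see [criteria_set()]).
#' @param cohort cohort-layout data frame.
#' @param predicate_id id used in error messages.
#' @return logical vector, one element per record, no `NA`s.
#' @keywords internal
eval_expression <- function(expr, cohort, predicate_id = "<anonymous>") {
  conf_stop <- function(...) {
    stop("criteria configuration error in predicate '", predicate_id, "': ", ...,
         call. = FALSE)
  }
  n <- nrow(cohort)
  if (!is.null(expr$flag)) {
    col <- cohort[[expr$flag]]
    if (is.null(col)) conf_stop("unknown flag token '", expr$flag, "'")
    return(!is.na(col) & col == 1L)
  }
  if (!is.null(expr$measurement)) {
    col <- cohort[[expr$measurement]]
    if (is.null(col)) conf_stop("unknown measurement token '", expr$measurement, "'")
    col <- as.numeric(col)
    if (!is.null(expr$outside)) {
      rng <- unlist(expr$outside)
      out <- !is.na(col) & (col < rng[1] | col > rng[2])
      return(out)
    }
    cmp <- switch(expr$cmp,
                  "<" = `<`, "<=" = `<=`, ">" = `>`, ">=" = `>=`,
                  conf_stop("unknown comparator '", expr$cmp, "'"))
    return(!is.na(col) & cmp(col, expr$value))
  }
  if (!is.null(expr$any_of)) {
    acc <- rep(FALSE, n)
    for (e in expr$any_of) {
      if (all(acc)) break  # short-circuit
      acc <- acc | eval_expression(e, cohort, predicate_id)
    }
    return(acc)
  }
  if (!is.null(expr$all_of)) {
    acc <- rep(TRUE, n)
    for (e in expr$all_of) {
      if (!any(acc)) break  # short-circuit
      acc <- acc & eval_expression(e, cohort, predicate_id)
    }
    return(acc)
  }
  conf_stop("expression is none of flag / threshold / outside / any_of / all_of")
}

#' Evaluate one predicate on one record
#'
#' @param record a one-row cohort-layout data frame (see [patient_record()]).
#' @param predicate a predicate from a criteria set (list with
#'   `predicate_id` and `expression`).
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_predicate <- function(record, predicate) {
  record <- normalise_cohort_columns(as.data.frame(record))
  as.logical(eval_expression(predicate$expression, record,
                             predicate$predicate_id %||% "<anonymous>"))[1]
}

# predicate-by-record logical matrix (rows = records, cols = predicates)
predicate_matrix <- function(cohort, criteria) {
  m <- vapply(criteria$predicates,
              function(p) eval_expression(p$expression, cohort, p$predicate_id),
              logical(nrow(cohort)))
  if (nrow(cohort) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- vapply(criteria$predicates, `[[`, character(1), "predicate_id")
  m
}

# combination rule -> positivity vector
combine_positives <- function(m, criteria) {
  if (criteria$combinator == "any_one") return(rowSums(m) > 0)
  # indian_sections: one true predicate in each of the three sections,
  # or any single cardiorespiratory-collapse criterion
  secs <- vapply(criteria$predicates, function(p) p$indian_section, character(1))
  hit <- function(section) {
    cols <- which(secs == section)
    if (length(cols) == 0) rep(FALSE, nrow(m)) else rowSums(m[, cols, drop = FALSE]) > 0
  }
  (hit("clinical_finding") & hit("investigation") & hit("intervention")) | hit("collapse")
}

#' Classify a cohort against a criteria set
#'
#' Applies the set's predicates to every record and derives the verdict
#' from positivity and vital outcome: a positive survivor is a maternal
#' near miss; a positive death is a maternal death identified by the set; a
#' death the set fails to flag is a missed maternal death.
#'
#' @param cohort an `mnm_cohort` or cohort-layout data frame.
#' @param criteria an `mnm_criteria` object (see [criteria_set()]) or a
#'   built-in set id string.
#' @return data frame with one row per record, input order preserved:
#'   `record_id`, `set_id`, `positive`, `matched` (`;`-joined predicate ids
#'   of every true predicate, sorted lexicographically), and `verdict`
#'   (`near_miss`, `maternal_death_identified`, `maternal_death_missed`, or
#'   `negative`).
#' @export
classify_cohort <- function(cohort, criteria) {
  if (is.character(criteria)) criteria <- criteria_set(criteria)
  stopifnot(inherits(criteria, "mnm_criteria"))
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) == 0) {
    return(data.frame(record_id = character(), set_id = character(),
                      positive = logical(), matched = character(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  m <- predicate_matrix(cohort, criteria)
  positive <- combine_positives(m, criteria)
  ord <- order(colnames(m))  # lexicographic, byte-stable output
  matched <- apply(m[, ord, drop = FALSE], 1L, function(row) {
    paste(colnames(m)[ord][row], collapse = ";")
  })
  died <- cohort$outcome == "died"
  verdict <- ifelse(positive,
                    ifelse(died, "maternal_death_identified", "near_miss"),
                    ifelse(died, "maternal_death_missed", "negative"))
  data.frame(record_id = cohort$record_id,
             set_id = criteria$set_id,
             positive = positive,
             matched = matched,
             verdict = verdict,
             stringsAsFactors = FALSE)
}

#' @rdname classify_cohort
#' @param record a one-row cohort-layout data frame.
#' @return `classify()` returns the one-row classification result for a
#'   single record.
#' @export
classify <- function(record, criteria) {
  record <- normalise_cohort_columns(as.data.frame(record))
  classify_cohort(record, criteria)
}

#' Screen a record for potentially life-threatening conditions
#'
#' The WHO PLTC screen is a coarser tier than near-miss classification:
#' its thresholds are looser (e.g. platelets < 100 000/mm3 against the
#' near-miss tool's <= 50 000) and it reports which of the four screening
#' categories a woman enters through.
#'
#' @param record one-row cohort-layout data frame.
#' @return character vector, a subset of `c("haemorrhagic", "hypertensive",
#'   "systemic", "management")`; empty when no screening predicate is met.
#' @export
pltc_screen <- function(record) {
  record <- normalise_cohort_columns(as.data.frame(record))
  hits <- pltc_screen_cohort(record)
  sort(names(hits)[vapply(hits, function(v) v[1], logical(1))])
}

#' @rdname pltc_screen
#' @param cohort cohort-layout data frame.
#' @return `pltc_screen_cohort()` returns a data frame of logicals with one
#'   column per screening category and one row per record.
#' @export
pltc_screen_cohort <- function(cohort) {
  screen <- criteria_set("pltc_screen")
  cohort <- as.data.frame(cohort)
  m <- predicate_matrix(cohort, screen)
  cats <- vapply(screen$predicates, function(p) p$pltc_category, character(1))
  out <- lapply(c(haemorrhagic = "haemorrhagic", hypertensive = "hypertensive",
                  systemic = "systemic", management = "management"),
                function(ct) rowSums(m[, cats == ct, drop = FALSE]) > 0)
  as.data.frame(out)
}
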