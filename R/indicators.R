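#' WHO near-miss process indicators
#'
#' Builds the cohort-level surveillance report for one criteria set:
#' near-miss and severe-maternal-outcome counts, missed deaths, and the
#' four WHO process indicators —
#' maternal near-miss ratio (MNM / live births x 1000), severe maternal
#' outcome ratio ((MNM + identified deaths) / live births x 1000),
#' mortality index (identified deaths / (MNM + identified deaths) x 100)
#' and the MNM:MD ratio (near misses per identified death). A lower
#' mortality index and a higher MNM:MD ratio indicate better quality of
#' care. All values are carried at full precision; [present_report()]
#' applies the conventional presentation rounding (1 decimal for ratios
#' and index, 2 for MNM:MD).
#'
#' Only deaths identified by the set count toward its severe maternal
#' outcomes; deaths the set misses are reported separately and never enter
#' the ratios. A set identifying no deaths has an undefined MNM:MD ratio,
#' reported as `NA` (serialised as `null`), never as infinity.
#'
#' @param n_near_miss near-miss count (positive survivors).
#' @param n_deaths_identified deaths flagged positive by the set.
#' @param n_deaths_missed deaths the set failed to flag.
#' @param live_births live-birth denominator (>= 1); this is the
#'   facility's live births, not the cohort size.
#' @param set_id label for the report row.
#' @return one-row data frame with counts and full-precision indicators.
#' @export
indicator_report <- function(n_near_miss, n_deaths_identified,
                             n_deaths_missed = 0L, live_births,
                             set_id = "custom") {
  if (live_births < 1) stop("live_births must be >= 1")
  stopifnot(n_near_miss >= 0, n_deaths_identified >= 0, n_deaths_missed >= 0)
  n_smo <- n_near_miss + n_deaths_identified
  data.frame(
    set_id = set_id,
    n_near_miss = as.integer(n_near_miss),
    n_deaths_identified = as.integer(n_deaths_identified),
    n_deaths_missed = as.integer(n_deaths_missed),
    n_smo = as.integer(n_smo),
    live_births = as.integer(live_births),
    mnm_ratio_per_1000 = n_near_miss / live_births * 1000,
    smo_ratio_per_1000 = n_smo / live_births * 1000,
    mortality_index_pct = if (n_smo > 0) n_deaths_identified / n_smo * 100 else 0,
    mnm_to_md_ratio = if (n_deaths_identified > 0) n_near_miss / n_deaths_identified else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @rdname indicator_report
#' @param results classification results from [classify_cohort()].
#' @param outcomes optional named character vector `record_id -> outcome`
#'   used to cross-check the verdicts; the verdicts themselves carry the
#'   outcome information.
#' @export
compute_report <- function(results, outcomes = NULL, live_births,
                           set_id = NULL) {
  if (!is.null(outcomes)) {
    if (!all(results$record_id %in% names(outcomes))) {
      stop("every result record_id needs an outcome")
    }
    died_v <- results$verdict %in% c("maternal_death_identified", "maternal_death_missed")
    if (!identical(unname(outcomes[results$record_id] == "died"), died_v)) {
      stop("verdicts are inconsistent with the supplied outcomes")
    }
  }
  indicator_report(
    n_near_miss = sum(results$verdict == "near_miss"),
    n_deaths_identified = sum(results$verdict == "maternal_death_identified"),
    n_deaths_missed = sum(results$verdict == "maternal_death_missed"),
    live_births = live_births,
    set_id = set_id %||% (if (nrow(results)) results$set_id[1] else "empty")
  )
}

#' @rdname indicator_report
#' @param report a report data frame from [indicator_report()] /
#'   [compare_criteria()].
#' @return `present_report()` returns the report with indicator columns
#'   rounded half-away-from-zero to presentation precision.
#' @export
present_report <- function(report) {
  report$mnm_ratio_per_1000 <- round_half_up(report$mnm_ratio_per_1000, 1)
  report$smo_ratio_per_1000 <- round_half_up(report$smo_ratio_per_1000, 1)
  report$mortality_index_pct <- round_half_up(report$mortality_index_pct, 1)
  report$mnm_to_md_ratio <- round_half_up(report$mnm_to_md_ratio, 2)
  report
}

#' Maternal mortality ratio per 100 000 live births
#'
#' @param n_deaths maternal deaths.
#' @param live_births live births (>= 1).
#' @return deaths per 100 000 live births, full precision.
#' @export
compute_mmr <- function(n_deaths, live_births) {
  if (live_births < 1) stop("live_births must be >= 1")
  n_deaths / live_births * 100000
}

#' Incidence of potentially life-threatening conditions per 1000 live births
#'
#' @param n_pltc women with a potentially life-threatening condition.
#' @inheritParams compute_mmr
#' @return PLTC incidence per 1000 live births, full precision.
#' @export
pltc_incidence <- function(n_pltc, live_births) {
  if (live_births < 1) stop("live_births must be >= 1")
  n_pltc / live_births * 1000
}

#' Case fatality by condition category
#'
#' One row per condition category present in the cohort: the number of
#' women with the condition (the PLTC denominator), deaths among them, the
#' case fatality rate (deaths / women with condition x 100), and — when
#' classification results are supplied — near misses among them. Categories
#' overlap, so a woman with several conditions contributes to each row and
#' counts need not sum to the cohort size. Categories with no women are
#' omitted (no denominator).
#'
#' @param cohort an `mnm_cohort` with `condition_category` annotations.
#' @param results optional [classify_cohort()] results used to fill the
#'   near-miss column.
#' @param categories categories to tabulate, in output order.
#' @return data frame with columns `condition`, `n_pltc`, `n_near_miss`,
#'   `n_deaths`, `case_fatality_pct`.
#' @export
case_fatality_table <- function(cohort, results = NULL,
                                categories = pltc_categories) {
  cohort <- as.data.frame(cohort)
  cond <- strsplit(ifelse(is.na(cohort$condition_category), "",
                          cohort$condition_category), ";", fixed = TRUE)
  nm_ids <- if (!is.null(results)) results$record_id[results$verdict == "near_miss"] else character()
  rows <- lapply(categories, function(ct) {
    in_ct <- vapply(cond, function(v) ct %in% v, logical(1))
    n <- sum(in_ct)
    if (n == 0) return(NULL)
    deaths <- sum(in_ct & cohort$outcome == "died")
    data.frame(condition = ct,
               n_pltc = n,
               n_near_miss = sum(cohort$record_id[in_ct] %in% nm_ids),
               n_deaths = deaths,
               case_fatality_pct = deaths / n * 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(condition = character(), n_pltc = integer(),
                      n_near_miss = integer(), n_deaths = integer(),
                      case_fatality_pct = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' @rdname case_fatality_table
#' @param n_deaths deaths among women with the condition.
#' @param n_pltc women with the condition.
#' @return `case_fatality()` returns the case fatality rate in percent.
#' @export
case_fatality <- function(n_deaths, n_pltc) {
  if (n_pltc < 1) stop("case fatality needs at least one woman with the condition")
  n_deaths / n_pltc * 100
}

#' Compare criteria sets on one cohort
#'
#' Classifies the identical cohort under each criteria set and returns one
#' indicator report per set, ordered by set id — the cross-criteria
#' comparison table of a near-miss surveillance audit.
#'
#' @param cohort an `mnm_cohort`.
#' @param criteria_sets list of `mnm_criteria` objects or set id strings;
#'   defaults to the seven shipped near-miss sets.
#' @return data frame with one [indicator_report()] row per criteria set.
#' @export
compare_criteria <- function(cohort, criteria_sets = comparison_sets()) {
  criteria_sets <- lapply(criteria_sets, function(cs) {
    if (is.character(cs)) criteria_set(cs) else cs
  })
  ids <- vapply(criteria_sets, function(cs) cs$set_id, character(1))
  criteria_sets <- criteria_sets[order(ids)]
  lb <- live_births(cohort)
  rows <- lapply(criteria_sets, function(cs) {
    compute_report(classify_cohort(cohort, cs), live_births = lb,
                   set_id = cs$set_id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
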