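# Independent brute-force evaluator used as the oracle for the rule
# engine: works on the list view of one record, enumerates every
# sub-expression naively (no vectorisation, no short-circuiting, no
# caching), and re-implements the combination rules from their
# definitions.

oracle_eval <- function(expr, rec) {
  if (!is.null(expr$flag)) return(expr$flag %in% rec$flags)
  if (!is.null(expr$measurement)) {
    val <- if (expr$measurement == "transfusion_units") {
      rec$transfusion_units
    } else if (expr$measurement %in% names(rec$measurements)) {
      rec$measurements[[expr$measurement]]
    } else {
      NA_real_
    }
    if (is.na(val)) return(FALSE)  # absence never asserts severity
    if (!is.null(expr$outside)) {
      rng <- unlist(expr$outside)
      return(val < rng[1] || val > rng[2])
    }
    return(switch(expr$cmp,
                  "<" = val < expr$value, "<=" = val <= expr$value,
                  ">" = val > expr$value, ">=" = val >= expr$value))
  }
  if (!is.null(expr$any_of)) {
    return(any(vapply(expr$any_of, oracle_eval, logical(1), rec = rec)))
  }
  if (!is.null(expr$all_of)) {
    return(all(vapply(expr$all_of, oracle_eval, logical(1), rec = rec)))
  }
  stop("oracle: malformed expression")
}

oracle_classify <- function(rec, criteria) {
  truth <- vapply(criteria$predicates,
                  function(p) oracle_eval(p$expression, rec), logical(1))
  ids <- vapply(criteria$predicates, `[[`, character(1), "predicate_id")
  if (criteria$combinator == "any_one") {
    positive <- any(truth)
  } else {
    secs <- vapply(criteria$predicates, `[[`, character(1), "indian_section")
    positive <- (any(truth[secs == "clinical_finding"]) &&
                 any(truth[secs == "investigation"]) &&
                 any(truth[secs == "intervention"])) ||
                any(truth[secs == "collapse"])
  }
  list(positive = positive, matched = paste(sort(ids[truth]), collapse = ";"))
}

# list view of one cohort row, independent of the package's internal one
oracle_record_view <- function(cohort, i) {
  row <- as.data.frame(cohort)[i, , drop = FALSE]
  vocab <- mnm_vocabulary()
  fl <- flag_tokens(vocab)
  ms <- setdiff(measurement_tokens(vocab), "transfusion_units")
  meas <- unlist(row[ms])
  list(flags = fl[unlist(row[fl]) == 1L],
       measurements = meas[!is.na(meas)],
       transfusion_units = row$transfusion_units)
}

# random records straddling every shipped threshold, for property tests
random_cohort <- function(n, seed, p_flag = 0.06, p_meas = 0.25) {
  set.seed(seed)
  vocab <- mnm_vocabulary()
  df <- data.frame(record_id = sprintf("r%06d", seq_len(n)),
                   outcome = sample(c("survived", "died"), n, TRUE, c(0.9, 0.1)),
                   stringsAsFactors = FALSE)
  for (fl in flag_tokens(vocab)) df[[fl]] <- stats::rbinom(n, 1, p_flag)
  ranges <- list(ph = c(6.7, 7.6), lactate_mmol_L = c(0, 12),
                 creatinine_mg_dL = c(0.3, 8), bilirubin_mg_dL = c(0.2, 15),
                 platelet_count_per_mm3 = c(5000, 450000),
                 spo2_pct_sustained_60min = c(55, 100),
                 pao2_fio2_mmHg = c(40, 500),
                 respiratory_rate_per_min = c(4, 60),
                 urine_output_mL_24h = c(0, 4000), urea_mmol_L = c(1, 40))
  for (tk in setdiff(measurement_tokens(vocab), "transfusion_units")) {
    v <- stats::runif(n, ranges[[tk]][1], ranges[[tk]][2])
    v[stats::runif(n) > p_meas] <- NA
    df[[tk]] <- v
  }
  df$transfusion_units <- stats::rbinom(n, 10, 0.12)
  new_cohort(df, live_births = max(n * 20L, 1L), label = "random")
}

# small Indian-style set with pairwise-disjoint sections, for exhaustive
# truth-table enumeration of the three-section/collapse combinator
disjoint_indian_set <- function() {
  validate_criteria(list(
    set_id = "indian_2014",
    combinator = "indian_sections",
    predicates = list(
      list(predicate_id = "tt_clin", category = "clinical",
           indian_section = "clinical_finding", expression = list(flag = "shock")),
      list(predicate_id = "tt_inv", category = "laboratory",
           indian_section = "investigation",
           expression = list(measurement = "platelet_count_per_mm3",
                             cmp = "<=", value = 50000)),
      list(predicate_id = "tt_int", category = "management",
           indian_section = "intervention", expression = list(flag = "hysterectomy")),
      list(predicate_id = "tt_collapse", category = "clinical",
           indian_section = "collapse", expression = list(flag = "cardiac_arrest"))
    )
  ))
}
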