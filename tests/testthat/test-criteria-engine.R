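who <- criteria_set("who_2011")
who_pred <- function(id) {
  ids <- vapply(who$predicates, `[[`, character(1), "predicate_id")
  who$predicates[[which(ids == id)]]
}

test_that("the WHO tool carries 25 indicators partitioned 12/7/6", {
  s <- criteria_summary(who)
  expect_identical(s$n_predicates, 25L)
  expect_identical(c(s$n_clinical, s$n_laboratory, s$n_management), c(12L, 7L, 6L))
})

test_that("threshold predicates evaluate on observed values and never on missingness", {
  thromb <- who_pred("who_lab_thrombocytopenia_le_50000")
  expect_true(evaluate_predicate(
    patient_record(measurements = c(platelet_count_per_mm3 = 40000)), thromb))
  expect_false(evaluate_predicate(
    patient_record(measurements = c(platelet_count_per_mm3 = 50001)), thromb))
  tx <- who_pred("who_mgmt_transfusion_ge_5")
  expect_true(evaluate_predicate(patient_record(transfusion_units = 5), tx))
  expect_false(evaluate_predicate(patient_record(transfusion_units = 4), tx))
  rr <- who_pred("who_clin_respiratory_rate")
  expect_false(evaluate_predicate(
    patient_record(measurements = c(respiratory_rate_per_min = 30)), rr))
  expect_true(evaluate_predicate(
    patient_record(measurements = c(respiratory_rate_per_min = 41)), rr))
  expect_true(evaluate_predicate(
    patient_record(measurements = c(respiratory_rate_per_min = 5)), rr))
  # an empty record satisfies no shipped predicate in any set
  empty <- patient_record("empty")
  for (id in builtin_set_ids()) {
    for (p in criteria_set(id)$predicates) {
      expect_false(evaluate_predicate(empty, p))
    }
  }
})

test_that("compound jaundice-with-pre-eclampsia fires by either route", {
  p <- who_pred("who_clin_jaundice_preeclampsia")
  expect_true(evaluate_predicate(patient_record(flags = "jaundice_with_preeclampsia"), p))
  expect_true(evaluate_predicate(patient_record(flags = c("jaundice", "preeclampsia")), p))
  expect_false(evaluate_predicate(patient_record(flags = "jaundice"), p))
})

test_that("classification verdicts combine positivity and outcome", {
  # a survivor whose only indicator is a 6-unit transfusion
  r <- patient_record("w", transfusion_units = 6)
  res_who <- classify(r, "who_2011")
  expect_true(res_who$positive)
  expect_identical(res_who$verdict, "near_miss")
  expect_identical(res_who$matched, "who_mgmt_transfusion_ge_5")
  expect_false(classify(r, "waterstone_2001")$positive)
  expect_true(classify(r, "global_network_2016")$positive)
  # a death no Mantel indicator catches
  d <- patient_record("d", outcome = "died", flags = "eclampsia")
  expect_identical(classify(d, "mantel_1998")$verdict, "maternal_death_missed")
  expect_identical(classify(d, "waterstone_2001")$verdict, "maternal_death_identified")
})

test_that("unknown tokens raise configuration errors naming the predicate", {
  bad <- list(set_id = "custom", combinator = "any_one",
              predicates = list(list(predicate_id = "bad_pred", category = "clinical",
                                     expression = list(flag = "no_such_token"))))
  expect_error(validate_criteria(bad), "bad_pred")
  expect_error(validate_criteria(list(set_id = "x", combinator = "indian_sections",
                                      predicates = list(list(predicate_id = "p", category = "clinical",
                                                             expression = list(flag = "shock"))))),
               "indian_section")
})

test_that("the Indian three-section rule needs one criterion per section or a collapse criterion", {
  # shipped roster: one clinical finding + one investigation, no intervention
  r <- patient_record(flags = "shock",
                      measurements = c(platelet_count_per_mm3 = 30000))
  expect_false(classify(r, "indian_2014")$positive)
  # adding an intervention completes the three sections
  r3 <- patient_record(flags = c("shock", "hysterectomy"),
                       measurements = c(platelet_count_per_mm3 = 30000))
  expect_true(classify(r3, "indian_2014")$positive)
  # a single collapse criterion short-cuts the rule
  expect_true(classify(patient_record(flags = "cardiac_arrest"), "indian_2014")$positive)
})

test_that("the Indian combinator truth table holds for all 16 section combinations", {
  cs <- disjoint_indian_set()
  for (clin in c(FALSE, TRUE)) for (inv in c(FALSE, TRUE)) {
    for (int in c(FALSE, TRUE)) for (col in c(FALSE, TRUE)) {
      rec <- patient_record(
        flags = c(if (clin) "shock", if (int) "hysterectomy", if (col) "cardiac_arrest"),
        measurements = if (inv) c(platelet_count_per_mm3 = 40000) else numeric())
      expected <- (clin && inv && int) || col
      got <- classify(rec, cs)
      expect_identical(got$positive, expected,
                       info = sprintf("clin=%s inv=%s int=%s collapse=%s", clin, inv, int, col))
      # and the independent oracle agrees
      expect_identical(oracle_classify(oracle_record_view(rec, 1), cs)$positive, expected)
    }
  }
})

test_that("the engine agrees with the brute-force oracle on random records", {
  co <- random_cohort(400, seed = 101)
  sets <- lapply(builtin_set_ids(), criteria_set)
  for (cs in sets) {
    res <- classify_cohort(co, cs)
    for (i in seq_len(nrow(co))) {
      expected <- oracle_classify(oracle_record_view(co, i), cs)
      expect_identical(res$positive[i], expected$positive)
      expect_identical(res$matched[i], expected$matched)
    }
  }
})

test_that("raising a threshold cut-off never turns a negative record positive", {
  co <- random_cohort(300, seed = 202)
  for (id in builtin_set_ids()) {
    cs <- criteria_set(id)
    for (k in seq_along(cs$predicates)) {
      e <- cs$predicates[[k]]$expression
      if (is.null(e$cmp) || !e$cmp %in% c(">", ">=")) next
      raised <- cs$predicates[[k]]
      raised$expression$value <- e$value * 1.5 + 1
      before <- vapply(seq_len(nrow(co)), function(i)
        evaluate_predicate(co[i, ], cs$predicates[[k]]), logical(1))
      after <- vapply(seq_len(nrow(co)), function(i)
        evaluate_predicate(co[i, ], raised), logical(1))
      expect_true(all(before | !after))  # satisfied set only shrinks
    }
  }
})

test_that("classify_cohort is pure, order-preserving and handles degenerate cohorts", {
  empty <- new_cohort(data.frame(record_id = character(), outcome = character()),
                      live_births = 10)
  expect_identical(nrow(classify_cohort(empty, "who_2011")), 0L)
  r <- patient_record("dup", flags = "shock")
  trip <- do.call(rbind, list(r, r, r))
  trip$record_id <- c("a", "b", "c")
  res <- classify_cohort(new_cohort(trip, live_births = 10), "who_2011")
  expect_identical(res$record_id, c("a", "b", "c"))
  expect_identical(unique(res$verdict), "near_miss")
  co <- generate_cohort(cohort_spec(n_records = 200, seed = 5))
  expect_identical(classify_cohort(co, "cdc_2017"), classify_cohort(co, "cdc_2017"))
})

test_that("the PLTC screen is a looser tier than near-miss classification", {
  r <- patient_record(measurements = c(platelet_count_per_mm3 = 90000))
  expect_identical(pltc_screen(r), "systemic")
  expect_false(classify(r, "who_2011")$positive)
  expect_identical(pltc_screen(patient_record(flags = "eclampsia")), "hypertensive")
  expect_identical(pltc_screen(patient_record()), character(0))
  multi <- pltc_screen(patient_record(flags = c("postpartum_haemorrhage", "severe_preeclampsia"),
                                      transfusion_units = 2))
  expect_identical(multi, c("haemorrhagic", "hypertensive", "management"))
})

test_that("every WHO five-unit transfusion positive is Global Network positive, not conversely", {
  gn <- criteria_set("global_network_2016")
  for (u in 1:8) {
    r <- patient_record(transfusion_units = u)
    w <- classify(r, who)$positive
    g <- classify(r, gn)$positive
    if (u >= 5) expect_true(w && g) else expect_true(!w && g)
  }
})
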