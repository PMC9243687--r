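# Published three-year referral-cohort counts used as fixture inputs:
# per-set (near miss, deaths identified, deaths missed) against 37 590
# live births.
published_counts <- list(
  mantel_1998 = c(324, 48, 9),
  waterstone_2001 = c(354, 21, 36),
  roberts_2008 = c(462, 52, 5),
  who_2011 = c(323, 57, 0),
  indian_2014 = c(280, 53, 4),
  global_network_2016 = c(483, 57, 0),
  cdc_2017 = c(588, 53, 4)
)
LB <- 37590L

test_that("indicator reports reproduce the published internally consistent cells", {
  reports <- do.call(rbind, lapply(names(published_counts), function(id) {
    k <- published_counts[[id]]
    indicator_report(k[1], k[2], k[3], LB, id)
  }))
  pres <- present_report(reports)
  rownames(pres) <- pres$set_id
  expect_equal(pres["who_2011", "mnm_ratio_per_1000"], 8.6)
  expect_equal(pres["who_2011", "smo_ratio_per_1000"], 10.1)
  expect_equal(pres["who_2011", "mortality_index_pct"], 15.0)
  expect_equal(round_half_up(reports$mnm_to_md_ratio[reports$set_id == "who_2011"], 1), 5.7)
  expect_equal(pres["mantel_1998", "mnm_ratio_per_1000"], 8.6)
  expect_equal(pres["mantel_1998", "smo_ratio_per_1000"], 9.9)
  expect_equal(pres["mantel_1998", "mortality_index_pct"], 12.9)
  expect_equal(pres["mantel_1998", "mnm_to_md_ratio"], 6.75)
  expect_equal(pres["waterstone_2001", "mnm_ratio_per_1000"], 9.4)
  expect_equal(pres["waterstone_2001", "smo_ratio_per_1000"], 10.0)
  expect_equal(pres["waterstone_2001", "mortality_index_pct"], 5.6)
  expect_equal(pres["roberts_2008", "smo_ratio_per_1000"], 13.7)
  expect_equal(pres["roberts_2008", "mortality_index_pct"], 10.1)
  expect_equal(pres["global_network_2016", "mnm_ratio_per_1000"], 12.8)
  expect_equal(pres["global_network_2016", "smo_ratio_per_1000"], 14.4)
  expect_equal(pres["global_network_2016", "mortality_index_pct"], 10.6)
  expect_equal(pres["global_network_2016", "mnm_to_md_ratio"], 8.47)
  expect_equal(pres["cdc_2017", "mnm_ratio_per_1000"], 15.6)
  expect_equal(pres["cdc_2017", "smo_ratio_per_1000"], 17.1)
  # SMO identity holds everywhere
  expect_identical(reports$n_smo, reports$n_near_miss + reports$n_deaths_identified)
})

test_that("headline rates: maternal mortality ratio and PLTC incidence", {
  expect_equal(round_half_up(compute_mmr(57, LB), 1), 151.6)
  expect_equal(round_half_up(pltc_incidence(1833, LB), 1), 48.8)
  expect_equal(compute_mmr(0, 1234), 0)
  expect_equal(compute_mmr(1, 100000), 1)
  expect_equal(pltc_incidence(0, LB), 0)
  expect_equal(pltc_incidence(LB, LB), 1000)
  expect_error(compute_mmr(1, 0), ">= 1")
})

test_that("degenerate reports: zero counts and undefined MNM:MD", {
  r <- indicator_report(0, 0, 0, 1000)
  expect_equal(r$mnm_ratio_per_1000, 0)
  expect_equal(r$smo_ratio_per_1000, 0)
  expect_equal(r$mortality_index_pct, 0)
  expect_true(is.na(r$mnm_to_md_ratio))
  expect_error(indicator_report(1, 0, 0, 0), ">= 1")
})

test_that("case fatality reproduces published condition rates and omits empty rows", {
  expect_equal(round_half_up(case_fatality(12, 90), 1), 13.3)
  expect_equal(case_fatality(0, 21), 0)
  expect_equal(round_half_up(case_fatality(19, 206), 1), 9.2)
  expect_error(case_fatality(0, 0), "at least one")
  rows <- do.call(rbind, list(
    patient_record("h1", outcome = "died", condition_category = c("haemorrhage", "medical")),
    patient_record("h2", condition_category = "haemorrhage"),
    patient_record("m1", condition_category = "medical")))
  co <- new_cohort(rows, live_births = 1000)
  tab <- case_fatality_table(co)
  expect_setequal(tab$condition, c("haemorrhage", "medical"))  # empty categories omitted
  expect_equal(tab$n_pltc[tab$condition == "haemorrhage"], 2)
  expect_equal(tab$case_fatality_pct[tab$condition == "haemorrhage"], 50)
  # overlapping categories: the death counts in both its categories
  expect_equal(tab$n_deaths[tab$condition == "medical"], 1)
})

test_that("deaths are conserved across identified and missed for every set", {
  co <- generate_cohort(cohort_spec(n_records = 600, seed = 11,
                                    atypical_death_fraction = 0.01))
  total_died <- sum(as.data.frame(co)$outcome == "died")
  for (id in setdiff(builtin_set_ids(), "pltc_screen")) {
    res <- classify_cohort(co, id)
    expect_identical(sum(res$verdict == "maternal_death_identified") +
                     sum(res$verdict == "maternal_death_missed"), total_died)
  }
})

test_that("indicators are invariant to scaling counts and denominator together", {
  base <- indicator_report(323, 57, 0, LB)
  for (k in c(2, 10)) {
    scaled <- indicator_report(323 * k, 57 * k, 0, LB * k)
    expect_equal(scaled$mnm_ratio_per_1000, base$mnm_ratio_per_1000)
    expect_equal(scaled$smo_ratio_per_1000, base$smo_ratio_per_1000)
    expect_equal(scaled$mortality_index_pct, base$mortality_index_pct)
    expect_equal(scaled$mnm_to_md_ratio, base$mnm_to_md_ratio)
  }
})

test_that("with deaths fixed, more near misses mean a lower mortality index and higher MNM:MD", {
  mi <- vapply(300:330, function(m) indicator_report(m, 57, 0, LB)$mortality_index_pct, numeric(1))
  ratio <- vapply(300:330, function(m) indicator_report(m, 57, 0, LB)$mnm_to_md_ratio, numeric(1))
  expect_true(all(diff(mi) < 0))
  expect_true(all(diff(ratio) > 0))
})

test_that("compare_criteria orders by set id and handles empty cohorts", {
  co <- generate_cohort(cohort_spec(n_records = 150, seed = 9))
  cmp <- compare_criteria(co)
  expect_identical(cmp$set_id, sort(setdiff(builtin_set_ids(), "pltc_screen")))
  empty <- new_cohort(data.frame(record_id = character()), live_births = 100)
  cmp0 <- compare_criteria(empty)
  expect_true(all(cmp0$n_smo == 0))
  expect_identical(cmp0$set_id, sort(setdiff(builtin_set_ids(), "pltc_screen")))
  # single-record cohort: the 6-unit transfusion survivor splits the sets
  one <- new_cohort(patient_record("w", transfusion_units = 6), live_births = 1000)
  cmp1 <- compare_criteria(one, list("who_2011", "waterstone_2001"))
  expect_equal(cmp1$n_near_miss[cmp1$set_id == "who_2011"], 1L)
  expect_equal(cmp1$n_near_miss[cmp1$set_id == "waterstone_2001"], 0L)
})
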