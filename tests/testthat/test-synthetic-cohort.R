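test_that("generation is deterministic given the spec and validates its inputs", {
  spec <- cohort_spec(n_records = 400, seed = 42)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  expect_error(cohort_spec(smo_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_spec(smo_fraction = 0.01, death_fraction = 0.02), "smo_fraction")
  expect_error(cohort_spec(smo_fraction = 0.2,
                           indicator_freqs_among_smo = c(shock = 0)),
               "indicator frequency")
})

test_that("a zero-SMO spec yields no WHO positives and no deaths", {
  co <- generate_cohort(cohort_spec(n_records = 300, smo_fraction = 0,
                                    death_fraction = 0, seed = 8))
  expect_identical(sum(classify_cohort(co, "who_2011")$positive), 0L)
  expect_identical(sum(as.data.frame(co)$outcome == "died"), 0L)
})

test_that("every generated record passes validation", {
  co <- generate_cohort(cohort_spec(n_records = 300, seed = 21))
  expect_identical(nrow(validate_cohort(co)), 0L)
})

test_that("default-scale cohorts land within binomial noise of the study counts", {
  spec <- cohort_spec(seed = 1)  # n = 1833
  co <- generate_cohort(spec)
  n <- nrow(co)
  who_pos <- sum(classify_cohort(co, "who_2011")$positive)
  sd_smo <- sqrt(n * spec$smo_fraction * (1 - spec$smo_fraction))
  expect_lt(abs(who_pos - n * spec$smo_fraction), 3 * sd_smo)  # target 380
  deaths <- sum(as.data.frame(co)$outcome == "died")
  sd_d <- sqrt(n * spec$death_fraction * (1 - spec$death_fraction))
  expect_lt(abs(deaths - n * spec$death_fraction), 3 * sd_d)   # target 57
})

test_that("marginal parameters are recovered within four binomial SDs at n = 20 000", {
  spec <- cohort_spec(n_records = 20000, seed = 33)
  rec <- recover_marginals(generate_cohort(spec), spec)
  expect_true(all(!rec$flagged))
  expect_true(all(abs(rec$z) <= 4))
  # degenerate prevalence recovers exactly
  spec1 <- cohort_spec(n_records = 500, seed = 2,
                       condition_prevalences = c(haemorrhage = 0.112, infection = 0.055,
                                                 hypertensive = 1.0, medical = 0.644,
                                                 labour_related = 0.009))
  rec1 <- recover_marginals(generate_cohort(spec1), spec1)
  expect_equal(rec1$observed[rec1$parameter == "prevalence_hypertensive"], 1.0)
  expect_equal(rec1$z[rec1$parameter == "prevalence_hypertensive"], 0)
})

test_that("an adversarial cohort of empty records is flagged against the default spec", {
  spec <- cohort_spec(n_records = 400, seed = 3)
  blank <- new_cohort(data.frame(record_id = sprintf("b%03d", 1:400),
                                 outcome = "survived"), live_births = spec$live_births)
  rec <- recover_marginals(blank, spec)
  z_hyp <- rec$z[rec$parameter == "prevalence_hypertensive"]
  expect_lt(z_hyp, -4)
  expect_true(rec$flagged[rec$parameter == "prevalence_hypertensive"])
})

test_that("deaths carry WHO indicators by construction; atypical deaths break other sets first", {
  co <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(sum(classify_cohort(co, "who_2011")$verdict == "maternal_death_missed"), 0L)
  expect_identical(sum(classify_cohort(co, "global_network_2016")$verdict == "maternal_death_missed"), 0L)
  co_at <- generate_cohort(cohort_spec(seed = 17, atypical_death_fraction = 0.02))
  missed_who <- sum(classify_cohort(co_at, "who_2011")$verdict == "maternal_death_missed")
  missed_mantel <- sum(classify_cohort(co_at, "mantel_1998")$verdict == "maternal_death_missed")
  expect_gt(missed_who, 0L)       # the atypical deaths carry no indicator at all
  expect_gte(missed_mantel, missed_who)  # Mantel's narrower roster misses at least as many
})
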