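#!/usr/bin/env Rscript
# Surveillance indicators, two ways:
#  (1) the cross-criteria comparison table computed on the synthetic
#      cohort (counts differ run to run only through the seed);
#  (2) the indicators recomputed from the published per-set counts — the
#      desk-scale reproduction that needs no cohort at all — plus the
#      headline maternal mortality ratio and PLTC incidence, and the
#      case-fatality table of the synthetic cohort.

suppressPackageStartupMessages(library(mnmtool))
if (!file.exists("results/synthetic_cohort.csv")) {
  stop("run analysis/01_simulate.R first")
}
prov <- jsonlite::read_json("results/synthetic_cohort_provenance.json")
cohort <- read_cohort("results/synthetic_cohort.csv",
                      live_births = prov$live_births, label = "synthetic")

cmp <- compare_criteria(cohort)
write.csv(cmp, "results/comparison_synthetic.csv", row.names = FALSE)
write_report_json(cmp, "results/comparison_synthetic.json")
cat("synthetic cohort, presentation precision:\n")
print(present_report(cmp)[, c("set_id", "n_near_miss", "n_deaths_identified",
                              "n_deaths_missed", "mnm_ratio_per_1000",
                              "mortality_index_pct", "mnm_to_md_ratio")])

published <- list(
  mantel_1998 = c(324, 48, 9), waterstone_2001 = c(354, 21, 36),
  roberts_2008 = c(462, 52, 5), who_2011 = c(323, 57, 0),
  indian_2014 = c(280, 53, 4), global_network_2016 = c(483, 57, 0),
  cdc_2017 = c(588, 53, 4))
LB <- 37590L
pub <- do.call(rbind, lapply(names(published), function(id) {
  k <- published[[id]]
  indicator_report(k[1], k[2], k[3], LB, id)
}))
write.csv(pub, "results/comparison_published_counts.csv", row.names = FALSE)
write_report_json(pub, "results/comparison_published_counts.json")
cat("\nindicators recomputed from the published counts:\n")
print(present_report(pub))
cat(sprintf("\nmaternal mortality ratio: %.1f per 100 000 live births\n",
            round_half_up(compute_mmr(57, LB), 1)))
cat(sprintf("PLTC incidence: %.1f per 1000 live births\n",
            round_half_up(pltc_incidence(1833, LB), 1)))

cf <- case_fatality_table(cohort, classify_cohort(cohort, "who_2011"))
cf$case_fatality_pct <- round_half_up(cf$case_fatality_pct, 1)
write.csv(cf, "results/case_fatality_synthetic.csv", row.names = FALSE)
cat("\ncase fatality by condition category (synthetic cohort):\n")
print(cf)
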