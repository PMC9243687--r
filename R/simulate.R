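#' Specification for a synthetic surveillance cohort
#'
#' Parameters of the synthetic generator, defaulting to the marginal
#' structure of a three-year single-facility referral cohort: 1833 women
#' with potentially life-threatening conditions against 37 590 live
#' births, 380 severe maternal outcomes (SMO), 57 maternal deaths, the
#' published condition-category prevalences, and the published WHO
#' severity-indicator frequencies among SMO records.
#'
#' Condition categories are drawn independently per record (they overlap,
#' so prevalences may sum past 1). SMO membership is Bernoulli
#' (`smo_fraction`); SMO records receive severity indicators; deaths are
#' drawn so the overall death fraction is `death_fraction`, assigned by
#' default only among SMO records carrying a clinical or management
#' indicator — every death is then identifiable by both the WHO tool and
#' any set covering its non-laboratory indicators. Setting
#' `atypical_death_fraction > 0` additionally kills non-SMO records (which
#' carry no WHO severity indicator) to exercise missed-death accounting.
#'
#' @param n_records cohort size (women with a potentially
#'   life-threatening condition).
#' @param live_births live-birth denominator.
#' @param smo_fraction probability a record is a severe maternal outcome.
#' @param death_fraction overall probability a record is a maternal death
#'   (must not exceed `smo_fraction`; deaths sit inside the SMO stratum).
#' @param condition_prevalences named probabilities of the five condition
#'   categories.
#' @param indicator_freqs_among_smo named probabilities, conditional on
#'   SMO, of the 25 WHO severity indicators (see
#'   `default_indicator_freqs()`).
#' @param transfusion_geom_prob parameter of the truncated geometric
#'   distribution of transfused units on 1..10.
#' @param transfused_fraction probability that a record without the
#'   five-plus-unit indicator is transfused 1-4 units (default 299/1725,
#'   consistent with 407 of 1833 women transfused overall of whom 108
#'   received >= 5 units).
#' @param atypical_death_fraction per-record death probability among
#'   non-SMO records (default 0: every death carries WHO indicators).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `mnm_cohort_spec`.
#' @export
cohort_spec <- function(n_records = 1833L,
                        live_births = 37590L,
                        smo_fraction = 380 / 1833,
                        death_fraction = 57 / 1833,
                        condition_prevalences = default_condition_prevalences(),
                        indicator_freqs_among_smo = default_indicator_freqs(),
                        transfusion_geom_prob = 0.45,
                        transfused_fraction = 299 / 1725,
                        atypical_death_fraction = 0,
                        seed = 1L) {
  spec <- structure(list(
    n_records = as.integer(n_records),
    live_births = as.integer(live_births),
    smo_fraction = smo_fraction,
    death_fraction = death_fraction,
    condition_prevalences = condition_prevalences,
    indicator_freqs_among_smo = indicator_freqs_among_smo,
    transfusion_geom_prob = transfusion_geom_prob,
    transfused_fraction = transfused_fraction,
    atypical_death_fraction = atypical_death_fraction,
    seed = as.integer(seed)
  ), class = "mnm_cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
default_condition_prevalences <- function() {
  c(haemorrhage = 0.112, infection = 0.055, hypertensive = 0.567,
    medical = 0.644, labour_related = 0.009)
}

#' @rdname cohort_spec
#' @export
default_indicator_freqs <- function() {
  c(
    # clinical
    acute_cyanosis = 0.000,
    gasping = 0.003,
    respiratory_rate_out = 0.047,
    shock = 0.082,
    cardiac_arrest = 0.008,
    oliguria_nonresponsive = 0.066,
    failure_to_form_clots = 0.245,
    loss_of_consciousness_gt_12h = 0.037,
    stroke = 0.005,
    uncontrollable_fits = 0.050,
    total_paralysis = 0.008,
    jaundice_with_preeclampsia = 0.016,
    # laboratory
    spo2_lt_90 = 0.126,
    ph_lt_7_1 = 0.037,
    pao2_fio2_lt_200 = 0.011,
    lactate_gt_5 = 0.011,
    creatinine_ge_3_5 = 0.063,
    thrombocytopenia_le_50000 = 0.268,
    bilirubin_gt_6 = 0.068,
    # management
    vasoactive_drug_use = 0.047,
    intubation_ventilation_gt_60min_non_anaesthetic = 0.211,
    hysterectomy = 0.092,
    dialysis_acute_renal_failure = 0.050,
    transfusion_ge_5 = 0.284,
    cpr = 0.079
  )
}

# indicator keys that are materialised as measurements, with the sampler
# for a value that satisfies the corresponding WHO threshold
measurement_indicators <- function() {
  list(
    respiratory_rate_out = list(token = "respiratory_rate_per_min",
                                draw = function(n) stats::runif(n, 41, 70)),
    spo2_lt_90 = list(token = "spo2_pct_sustained_60min",
                      draw = function(n) stats::runif(n, 60, 89.5)),
    ph_lt_7_1 = list(token = "ph",
                     draw = function(n) stats::runif(n, 6.8, 7.09)),
    pao2_fio2_lt_200 = list(token = "pao2_fio2_mmHg",
                            draw = function(n) stats::runif(n, 50, 199)),
    lactate_gt_5 = list(token = "lactate_mmol_L",
                        draw = function(n) stats::runif(n, 5.1, 15)),
    creatinine_ge_3_5 = list(token = "creatinine_mg_dL",
                             draw = function(n) stats::runif(n, 3.5, 10)),
    thrombocytopenia_le_50000 = list(token = "platelet_count_per_mm3",
                                     draw = function(n) stats::runif(n, 5000, 49999)),
    bilirubin_gt_6 = list(token = "bilirubin_mg_dL",
                          draw = function(n) stats::runif(n, 6.1, 25))
  )
}

indicator_is_lab <- function(keys) {
  keys %in% c("spo2_lt_90", "ph_lt_7_1", "pao2_fio2_lt_200", "lactate_gt_5",
              "creatinine_ge_3_5", "thrombocytopenia_le_50000", "bilirubin_gt_6")
}

validate_cohort_spec <- function(spec) {
  probs <- c(spec$smo_fraction, spec$death_fraction,
             spec$condition_prevalences, spec$indicator_freqs_among_smo,
             spec$transfused_fraction, spec$atypical_death_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("cohort spec domain error: all probabilities must lie in [0, 1]")
  }
  if (spec$death_fraction > spec$smo_fraction) {
    stop("cohort spec domain error: death_fraction must not exceed smo_fraction (deaths are severe maternal outcomes)")
  }
  if (spec$transfusion_geom_prob <= 0 || spec$transfusion_geom_prob >= 1) {
    stop("cohort spec domain error: transfusion_geom_prob must lie in (0, 1)")
  }
  if (spec$n_records < 0 || spec$live_births < 1) {
    stop("cohort spec domain error: need n_records >= 0 and live_births >= 1")
  }
  missing_names <- setdiff(names(default_condition_prevalences()),
                           names(spec$condition_prevalences))
  if (length(missing_names)) {
    stop("cohort spec domain error: condition_prevalences missing ",
         paste(missing_names, collapse = ", "))
  }
  if (spec$smo_fraction > 0 && sum(spec$indicator_freqs_among_smo) == 0) {
    stop("cohort spec domain error: smo_fraction > 0 requires at least one indicator frequency > 0")
  }
  invisible(spec)
}

# Deflate the published conditional indicator frequencies p (conditional on
# carrying >= 1 indicator, i.e. on being an SMO) to base Bernoulli rates
# q = c * p such that independent draws conditioned on >= 1 success
# reproduce p exactly: c solves 1 - prod(1 - c * p) = c.
calibrate_indicator_probs <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(numeric(0))
  f <- function(cc) (1 - prod(1 - cc * p)) - cc
  # f(0+) > 0 when sum(p) > 1 (always true for the shipped frequencies);
  # f(1) = P(any) - 1 < 0, so a root lies in (0, 1)
  if (f(1) >= 0) return(p)  # already self-consistent
  cc <- stats::uniroot(f, c(1e-12, 1), tol = 1e-12)$root
  cc * p
}

# truncated geometric on {lo..hi}: P(k) proportional to (1-prob)^(k-1)
draw_truncated_geometric <- function(n, prob, lo, hi) {
  support <- lo:hi
  w <- (1 - prob)^(support - 1)
  sample(support, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]. Indicator vectors of SMO records
#' are independent Bernoulli draws conditioned on carrying at least one
#' indicator (rejection sampling from calibrated base rates, so that the
#' observed conditional frequencies match the spec exactly in
#' expectation). Measurement-type indicators materialise as values drawn
#' uniformly from a clinically bounded severe range; flags materialise as
#' flag columns. A light consistency layer links condition categories to
#' screen-tier flags (so the PLTC screen and case-fatality table have
#' signal) and severe condition flags to SMO records (so the
#' condition-based Waterstone/Mantel sets have signal); these correlations
#' are the only ones injected — the published marginals carry no joint
#' structure.
#'
#' @param spec an `mnm_cohort_spec` from [cohort_spec()].
#' @return an [new_cohort()] cohort; deterministic given `spec` (including
#'   its seed).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_records
  flags <- flag_tokens()
  meas <- setdiff(measurement_tokens(), "transfusion_units")
  df <- data.frame(record_id = sprintf("S%05d", seq_len(n)),
                   outcome = rep("survived", n),
                   timing = sample(timing_levels[c(1, 2, 3, 5, 6)], n, replace = TRUE,
                                   prob = c(52, 164, 1462, 139, 16)),
                   condition_category = rep("", n),
                   stringsAsFactors = FALSE)
  for (tk in flags) df[[tk]] <- 0L
  for (tk in meas) df[[tk]] <- NA_real_
  df$transfusion_units <- 0L
  if (n == 0) return(new_cohort(df, spec$live_births, label = "synthetic"))

  # overlapping condition categories, independent draws
  cond <- vapply(names(default_condition_prevalences()), function(ct) {
    stats::rbinom(n, 1, spec$condition_prevalences[[ct]]) == 1
  }, logical(n))
  if (n == 1L) cond <- matrix(cond, nrow = 1, dimnames = list(NULL, names(default_condition_prevalences())))
  df$condition_category <- apply(cond, 1, function(row) {
    paste(colnames(cond)[row], collapse = ";")
  })

  # SMO stratum and its severity indicators
  smo <- stats::rbinom(n, 1, spec$smo_fraction) == 1
  n_smo <- sum(smo)
  ind_keys <- character(0)
  ind_mat <- NULL
  if (n_smo > 0) {
    q <- calibrate_indicator_probs(spec$indicator_freqs_among_smo)
    ind_keys <- names(q)
    ind_mat <- matrix(FALSE, n_smo, length(q), dimnames = list(NULL, ind_keys))
    todo <- seq_len(n_smo)
    while (length(todo)) {  # rejection: condition on >= 1 indicator
      draw <- matrix(stats::rbinom(length(todo) * length(q), 1, rep(q, each = length(todo))) == 1,
                     nrow = length(todo))
      ind_mat[todo, ] <- draw
      todo <- todo[rowSums(draw) == 0]
    }
    smo_rows <- which(smo)
    mi <- measurement_indicators()
    for (k in ind_keys) {
      hit <- smo_rows[ind_mat[, k]]
      if (length(hit) == 0) next
      if (k %in% names(mi)) {
        df[[mi[[k]]$token]][hit] <- mi[[k]]$draw(length(hit))
      } else if (k == "transfusion_ge_5") {
        df$transfusion_units[hit] <- draw_truncated_geometric(
          length(hit), spec$transfusion_geom_prob, 5L, 10L)
      } else {
        df[[k]][hit] <- 1L
      }
    }
    # consistency layer: SMO records acquire the severe form of their
    # condition category so condition-based sets see them
    sev_hyp <- smo_rows[cond[smo_rows, "hypertensive"]]
    if (length(sev_hyp)) {
      pick <- sample(c("severe_preeclampsia", "eclampsia", "hellp"),
                     length(sev_hyp), replace = TRUE, prob = c(0.55, 0.12, 0.33))
      for (fl in unique(pick)) df[[fl]][sev_hyp[pick == fl]] <- 1L
    }
    sev_hae <- smo_rows[cond[smo_rows, "haemorrhage"]]
    if (length(sev_hae)) df$severe_bleeding[sev_hae] <- 1L
    sev_inf <- smo_rows[cond[smo_rows, "infection"]]
    if (length(sev_inf)) df$severe_sepsis[sev_inf] <- 1L
    # flag-implies-measurement: HELLP without the severe-thrombocytopenia
    # indicator still shows a sub-screen platelet count
    hellp_rows <- which(df$hellp == 1L & is.na(df$platelet_count_per_mm3))
    if (length(hellp_rows)) {
      df$platelet_count_per_mm3[hellp_rows] <- stats::runif(length(hellp_rows), 51000, 99000)
    }
  }

  # screen-tier flags for every record, by condition category (these do not
  # satisfy any near-miss predicate)
  screen_map <- list(
    haemorrhage = c("postpartum_haemorrhage", "placental_abruption",
                    "placenta_praevia", "ectopic_pregnancy"),
    hypertensive = c("hypertensive_urgency", "preeclampsia"),
    infection = "sepsis",
    medical = "seizures"
  )
  for (ct in names(screen_map)) {
    rows <- which(cond[, ct])
    if (length(rows) == 0) next
    pick <- sample(screen_map[[ct]], length(rows), replace = TRUE)
    for (fl in unique(pick)) df[[fl]][rows[pick == fl]] <- 1L
  }

  # transfusion of 1-4 units among records without the >= 5-unit indicator
  no5 <- which(df$transfusion_units == 0L)
  if (length(no5)) {
    tx <- no5[stats::rbinom(length(no5), 1, spec$transfused_fraction) == 1]
    if (length(tx)) {
      df$transfusion_units[tx] <- draw_truncated_geometric(
        length(tx), spec$transfusion_geom_prob, 1L, 4L)
    }
  }

  # deaths: overall fraction death_fraction, assigned among SMO records
  # carrying a clinical or management (non-laboratory) indicator
  n_deaths <- stats::rbinom(1, n, spec$death_fraction)
  if (n_deaths > 0 && n_smo > 0) {
    nonlab <- rowSums(ind_mat[, !indicator_is_lab(ind_keys), drop = FALSE]) > 0
    eligible <- which(smo)[nonlab]
    if (n_deaths > length(eligible)) n_deaths <- length(eligible)
    died <- if (length(eligible) == 1) eligible else sample(eligible, n_deaths)
    df$outcome[died] <- "died"
  }
  if (spec$atypical_death_fraction > 0) {
    non_smo <- which(!smo)
    atyp <- non_smo[stats::rbinom(length(non_smo), 1, spec$atypical_death_fraction) == 1]
    df$outcome[atyp] <- "died"
  }

  new_cohort(df, spec$live_births, label = "synthetic")
}

#' Check a generated cohort against its generating parameters
#'
#' Compares observed marginal frequencies with the spec's targets and
#' standardises each deviation by its binomial standard error. The SMO
#' stratum is identified operationally as the WHO-positive records (by
#' construction the same stratum). Deviations with |z| > 4 are flagged.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param spec the generating `mnm_cohort_spec`.
#' @return data frame with columns `parameter`, `target`, `observed`, `n`,
#'   `z`, `flagged`.
#' @export
recover_marginals <- function(cohort, spec) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  rows <- list()
  note <- function(parameter, target, observed, size) {
    se <- sqrt(target * (1 - target) / max(size, 1))
    z <- if (se == 0) {
      if (isTRUE(all.equal(observed, target))) 0 else Inf
    } else {
      (observed - target) / se
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, target = target, observed = observed,
      n = size, z = z, flagged = abs(z) > 4, stringsAsFactors = FALSE)
  }
  cond <- strsplit(ifelse(is.na(cohort$condition_category), "",
                          cohort$condition_category), ";", fixed = TRUE)
  for (ct in names(spec$condition_prevalences)) {
    obs <- mean(vapply(cond, function(v) ct %in% v, logical(1)))
    note(paste0("prevalence_", ct), spec$condition_prevalences[[ct]], obs, n)
  }
  who_pos <- classify_cohort(cohort, criteria_set("who_2011"))$positive
  note("smo_fraction", spec$smo_fraction, mean(who_pos), n)
  note("death_fraction", spec$death_fraction + spec$atypical_death_fraction * (1 - spec$smo_fraction),
       mean(cohort$outcome == "died"), n)
  n_smo <- sum(who_pos)
  if (n_smo > 0) {
    mi <- measurement_indicators()
    for (k in names(spec$indicator_freqs_among_smo)) {
      p <- spec$indicator_freqs_among_smo[[k]]
      obs <- if (k %in% names(mi)) {
        tok <- mi[[k]]$token
        val <- cohort[[tok]][who_pos]
        mean(!is.na(val) & observed_satisfies(k, val))
      } else if (k == "transfusion_ge_5") {
        mean(cohort$transfusion_units[who_pos] >= 5)
      } else {
        mean(cohort[[k]][who_pos] == 1L)
      }
      note(paste0("indicator_", k), p, obs, n_smo)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# does an observed measurement value satisfy the WHO threshold linked to
# an indicator key? (used only for marginal recovery)
observed_satisfies <- function(key, value) {
  switch(key,
         respiratory_rate_out = value > 40 | value < 6,
         spo2_lt_90 = value < 90,
         ph_lt_7_1 = value < 7.1,
         pao2_fio2_lt_200 = value < 200,
         lactate_gt_5 = value > 5,
         creatinine_ge_3_5 = value >= 3.5,
         thrombocytopenia_le_50000 = value <= 50000,
         bilirubin_gt_6 = value > 6,
         stop("unknown measurement indicator key: ", key))
}
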