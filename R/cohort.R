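#' Patient records and cohorts
#'
#' A cohort is a data frame with one row per woman: identifier, vital
#' outcome, optional timing and condition-category annotations, one 0/1
#' column per flag token, one numeric column per measurement token (`NA` =
#' not measured) and an integer `transfusion_units` column. The
#' `transfusion_units` column doubles as the measurement of the same name:
#' it is the one datum, exposed once, with 0 meaning "no transfusion
#' recorded" (a real value, never missing). The cohort carries its
#' live-birth denominator as an attribute because surveillance denominators
#' (live births in the catchment period) exceed the size of the severe
#' cohort being classified.
#'
#' @param data data frame of records in the cohort column layout; missing
#'   flag/measurement columns are added (flags 0, measurements `NA`).
#' @param live_births positive integer denominator for per-1000 and
#'   per-100 000 rates.
#' @param label cohort label used in reports.
#' @param vocabulary vocabulary data frame, see [mnm_vocabulary()].
#' @return A data frame of class `mnm_cohort` with attributes `live_births`
#'   and `label`.
#' @export
new_cohort <- function(data, live_births, label = "cohort",
                       vocabulary = mnm_vocabulary()) {
  if (missing(live_births) || is.null(live_births)) {
    stop("live_births is mandatory: the denominator is the facility's live births, not the cohort size")
  }
  live_births <- as.integer(live_births)
  if (is.na(live_births) || live_births < 1) stop("live_births must be >= 1")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data <- normalise_cohort_columns(data, vocabulary)
  if (anyDuplicated(data$record_id)) {
    stop("record_id must be unique within a cohort; duplicated: ",
         paste(unique(data$record_id[duplicated(data$record_id)]), collapse = ", "))
  }
  structure(data,
            live_births = live_births,
            label = label,
            class = c("mnm_cohort", "data.frame"))
}

# Fill in any missing schema columns and order them canonically.
normalise_cohort_columns <- function(data, vocabulary = mnm_vocabulary()) {
  flags <- flag_tokens(vocabulary)
  meas <- setdiff(measurement_tokens(vocabulary), "transfusion_units")
  n <- nrow(data)
  if (is.null(data$record_id)) data$record_id <- as.character(seq_len(n))
  data$record_id <- as.character(data$record_id)
  if (is.null(data$outcome)) data$outcome <- rep("survived", n)
  if (is.null(data$timing)) data$timing <- rep(NA_character_, n)
  data$timing <- as.character(data$timing)
  data$timing[!is.na(data$timing) & !nzchar(trimws(data$timing))] <- NA_character_
  if (is.null(data$condition_category)) data$condition_category <- rep("", n)
  data$condition_category[is.na(data$condition_category)] <- ""
  for (tk in flags) {
    if (is.null(data[[tk]])) data[[tk]] <- rep(0L, n)
    v <- data[[tk]]
    v[is.na(v)] <- 0L
    data[[tk]] <- as.integer(v)
  }
  for (tk in meas) {
    if (is.null(data[[tk]])) data[[tk]] <- rep(NA_real_, n)
    data[[tk]] <- as.numeric(data[[tk]])
  }
  if (is.null(data$transfusion_units)) data$transfusion_units <- rep(0L, n)
  tu <- data$transfusion_units
  tu[is.na(tu)] <- 0L
  data$transfusion_units <- as.integer(tu)
  data[, c("record_id", "outcome", "timing", "condition_category",
           flags, meas, "transfusion_units"), drop = FALSE]
}

#' @rdname new_cohort
#' @param x object to test.
#' @export
is_cohort <- function(x) inherits(x, "mnm_cohort")

#' @rdname new_cohort
#' @export
live_births <- function(x) {
  lb <- attr(x, "live_births")
  if (is.null(lb)) stop("object has no live_births attribute")
  lb
}

#' Construct a single patient record
#'
#' Convenience constructor returning a one-row data frame in the cohort
#' column layout, directly usable with [classify()] and [pltc_screen()].
#'
#' @param record_id identifier string.
#' @param outcome `"survived"` or `"died"`.
#' @param flags character vector of flag tokens present.
#' @param measurements named numeric vector of observed measurement values
#'   (canonical units); anything not named is missing. A
#'   `transfusion_units` entry is routed to the `transfusion_units` column.
#' @param transfusion_units non-negative integer units of whole blood or
#'   packed red cells (pooled), 0 = none recorded.
#' @param timing optional timing token (see cohort CSV dialect).
#' @param condition_category optional character vector of condition
#'   categories (`haemorrhage`, `infection`, `hypertensive`, `medical`,
#'   `labour_related`).
#' @param vocabulary vocabulary data frame.
#' @return one-row data frame in the cohort layout.
#' @export
patient_record <- function(record_id = "r1", outcome = "survived",
                           flags = character(), measurements = numeric(),
                           transfusion_units = 0L, timing = NA_character_,
                           condition_category = character(),
                           vocabulary = mnm_vocabulary()) {
  rec <- data.frame(record_id = as.character(record_id),
                    outcome = outcome,
                    timing = timing,
                    condition_category = paste(condition_category, collapse = ";"),
                    stringsAsFactors = FALSE)
  for (fl in flags) rec[[fl]] <- 1L
  if (length(measurements)) {
    if (is.null(names(measurements)) || any(names(measurements) == "")) {
      stop("measurements must be a fully named numeric vector")
    }
    for (tk in names(measurements)) {
      if (tk == "transfusion_units") transfusion_units <- measurements[[tk]]
      else rec[[tk]] <- as.numeric(measurements[[tk]])
    }
  }
  rec$transfusion_units <- as.integer(transfusion_units)
  # keep unknown tokens visible to validate_record() rather than erroring here
  unknown <- setdiff(c(flags, setdiff(names(measurements), "transfusion_units")),
                     vocabulary$token)
  if (length(unknown) == 0) rec <- normalise_cohort_columns(rec, vocabulary)
  rec
}

# list-form view of row i of a cohort-layout data frame
as_record_list <- function(data, i = 1L, vocabulary = mnm_vocabulary()) {
  row <- data[i, , drop = FALSE]
  schema <- c("record_id", "outcome", "timing", "condition_category", "transfusion_units")
  flags_all <- intersect(names(row), flag_tokens(vocabulary))
  meas_all <- intersect(names(row), setdiff(measurement_tokens(vocabulary), "transfusion_units"))
  extra <- setdiff(names(row), c(schema, flag_tokens(vocabulary), measurement_tokens(vocabulary)))
  flags_on <- flags_all[vapply(flags_all, function(tk) isTRUE(row[[tk]] == 1L), logical(1))]
  meas <- vapply(meas_all, function(tk) as.numeric(row[[tk]]), numeric(1))
  meas <- meas[!is.na(meas)]
  cond <- row$condition_category %||% ""
  list(
    record_id = row$record_id,
    outcome = row$outcome,
    timing = row$timing,
    condition_category = if (is.na(cond) || cond == "") character() else strsplit(cond, ";", fixed = TRUE)[[1]],
    flags = unname(flags_on),
    measurements = meas,
    transfusion_units = row$transfusion_units,
    extra_fields = extra
  )
}

#' Validate a patient record against the vocabulary
#'
#' Report-style validation: returns a data frame of violations (possibly
#' empty) and never throws on record content. Each violation names the
#' offending field and token.
#'
#' @param record a one-row data frame in the cohort layout (e.g. from
#'   [patient_record()]) or a list with elements `flags`, `measurements`,
#'   `transfusion_units`, `outcome`.
#' @param vocabulary vocabulary data frame.
#' @return data frame with columns `field`, `token`, `message`; zero rows
#'   when the record is valid.
#' @export
validate_record <- function(record, vocabulary = mnm_vocabulary()) {
  if (is.data.frame(record)) record <- as_record_list(record, 1L, vocabulary)
  violations <- list()
  add <- function(field, token, message) {
    violations[[length(violations) + 1L]] <<- data.frame(
      field = field, token = token, message = message, stringsAsFactors = FALSE)
  }
  unknown_flags <- setdiff(record$flags, flag_tokens(vocabulary))
  for (tk in c(unknown_flags, record$extra_fields %||% character())) {
    add("flags", tk, sprintf("token '%s' is not in the vocabulary", tk))
  }
  unknown_meas <- setdiff(names(record$measurements), measurement_tokens(vocabulary))
  for (tk in unknown_meas) {
    add("measurements", tk, sprintf("measurement token '%s' is not in the vocabulary", tk))
  }
  if (!isTRUE(record$outcome %in% c("survived", "died"))) {
    add("outcome", record$outcome %||% NA_character_,
        "outcome must be 'survived' or 'died'")
  }
  if (!is.null(record$timing) && !is.na(record$timing) &&
      !record$timing %in% timing_levels) {
    add("timing", record$timing, "unknown timing value")
  }
  bad_cond <- setdiff(record$condition_category %||% character(), pltc_categories)
  for (tk in bad_cond) add("condition_category", tk, "unknown condition category")
  tu <- record$transfusion_units %||% 0L
  if (is.na(tu) || tu < 0 || tu != trunc(tu)) {
    add("transfusion_units", as.character(tu),
        "transfusion_units must be a non-negative integer (whole units)")
  }
  known_meas <- record$measurements[names(record$measurements) %in% measurement_tokens(vocabulary)]
  if (length(known_meas) && any(!is.finite(unlist(known_meas)))) {
    bad <- names(known_meas)[!is.finite(unlist(known_meas))]
    for (tk in bad) add("measurements", tk, "measurement value must be finite (omit if not measured)")
  }
  if (length(violations) == 0) {
    return(data.frame(field = character(), token = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, violations)
}

#' Validate every record in a cohort
#'
#' @param cohort an `mnm_cohort` or cohort-layout data frame.
#' @param vocabulary vocabulary data frame.
#' @return data frame of violations with a `row` column; zero rows when the
#'   cohort is valid.
#' @export
validate_cohort <- function(cohort, vocabulary = mnm_vocabulary()) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    v <- validate_record(as_record_list(cohort, i, vocabulary), vocabulary)
    if (nrow(v)) cbind(row = i, v) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    data.frame(row = integer(), field = character(), token = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    out
  }
}
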