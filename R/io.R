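#' Read a cohort from CSV
#'
#' The cohort CSV dialect has a mandatory header row and the columns
#' `record_id`, `outcome` (`survived|died`), optional `timing`, optional
#' `condition_category` (semicolon-joined category tokens), one 0/1 column
#' per flag token (empty = 0), one numeric column per measurement token
#' (empty = not measured), and `transfusion_units` (integer, empty = 0).
#' UTF-8, comma separator, `.` decimal. Unknown columns are rejected
#' unless `allow_extra = TRUE`.
#'
#' An optional first line `#units: token=umol/L[;token=umol/L...]` declares
#' that a creatinine or bilirubin column arrives in µmol/L; those columns
#' are converted to the canonical mg/dL at ingest (÷ 88.4 and ÷ 17.1).
#'
#' @param path CSV file path.
#' @param live_births mandatory live-birth denominator; it is never
#'   inferred from the row count because surveillance denominators exceed
#'   the severe cohort being classified.
#' @param label cohort label.
#' @param allow_extra keep (and ignore) columns outside the dialect.
#' @param vocabulary vocabulary data frame.
#' @return an [new_cohort()] cohort.
#' @export
read_cohort <- function(path, live_births, label = basename(path),
                        allow_extra = FALSE, vocabulary = mnm_vocabulary()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  unit_decl <- character(0)
  skip <- 0L
  if (startsWith(first, "#units:")) {
    skip <- 1L
    decl <- trimws(sub("^#units:", "", first))
    if (nzchar(decl)) {
      parts <- strsplit(decl, ";", fixed = TRUE)[[1]]
      kv <- strsplit(parts, "=", fixed = TRUE)
      unit_decl <- stats::setNames(vapply(kv, `[`, character(1), 2),
                                   trimws(vapply(kv, `[`, character(1), 1)))
    }
  }
  raw <- utils::read.csv(path, skip = skip, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  schema_cols <- c("record_id", "outcome", "timing", "condition_category",
                   flag_tokens(vocabulary), measurement_tokens(vocabulary))
  unknown <- setdiff(names(raw), schema_cols)
  if (length(unknown) && !allow_extra) {
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "),
         " (use allow_extra = TRUE to ignore)")
  }
  raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  if (is.null(raw$record_id)) stop("cohort file must have a record_id column")

  parse_numeric_col <- function(col_name) {
    v <- raw[[col_name]]
    v[!nzchar(trimws(v))] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(sprintf("parse failure in %s: row %d, column '%s': '%s' is not numeric",
                   path, bad[1] + skip + 1L, col_name, v[bad[1]]))
    }
    out
  }
  for (tk in intersect(names(raw), measurement_tokens(vocabulary))) {
    val <- parse_numeric_col(tk)
    if (tk %in% names(unit_decl)) {
      conv <- unit_decl[[tk]]
      if (!conv %in% c("umol/L", "µmol/L")) {
        stop("unsupported unit declaration '", conv, "' for column ", tk)
      }
      analyte <- switch(tk, creatinine_mg_dL = "creatinine",
                        bilirubin_mg_dL = "bilirubin",
                        stop("unit conversion is only supported for creatinine_mg_dL and bilirubin_mg_dL"))
      val <- umol_to_mg_dl(val, analyte)
    }
    raw[[tk]] <- val
  }
  for (tk in intersect(names(raw), flag_tokens(vocabulary))) {
    v <- trimws(raw[[tk]])
    v[!nzchar(v)] <- "0"
    if (!all(v %in% c("0", "1"))) {
      bad <- which(!v %in% c("0", "1"))[1]
      stop(sprintf("parse failure in %s: row %d, column '%s': flag values must be 0/1/empty",
                   path, bad + skip + 1L, tk))
    }
    raw[[tk]] <- as.integer(v)
  }
  if (!is.null(raw$transfusion_units) && is.character(raw$transfusion_units)) {
    raw$transfusion_units <- parse_numeric_col("transfusion_units")
  }
  cohort <- new_cohort(raw, live_births = live_births, label = label,
                       vocabulary = vocabulary)
  violations <- validate_cohort(cohort, vocabulary)
  if (nrow(violations)) {
    msgs <- sprintf("row %d: %s", violations$row, violations$message)
    stop("cohort validation failed (", nrow(violations), " violation(s)):\n",
         paste(utils::head(msgs, 10), collapse = "\n"))
  }
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: measurements print at full precision (17
#' significant digits) so a write/read round trip reproduces the cohort
#' field-by-field, including measurement missingness (empty cells).
#'
#' @param cohort an `mnm_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (tk in setdiff(measurement_tokens(), "transfusion_units")) {
    v <- df[[tk]]
    df[[tk]] <- ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an indicator report as JSON
#'
#' Serialises full-precision values together with presentation-rounded
#' twins (1 decimal for ratios and the mortality index, 2 for the MNM:MD
#' ratio). An undefined MNM:MD ratio (no identified deaths) serialises as
#' `null`. The shape is described by the shipped schema
#' `inst/extdata/report.schema.json`.
#'
#' @param report data frame from [indicator_report()] or
#'   [compare_criteria()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  pres <- present_report(report)
  items <- lapply(seq_len(nrow(report)), function(i) {
    list(
      set_id = report$set_id[i],
      counts = list(
        n_near_miss = report$n_near_miss[i],
        n_deaths_identified = report$n_deaths_identified[i],
        n_deaths_missed = report$n_deaths_missed[i],
        n_smo = report$n_smo[i],
        live_births = report$live_births[i]
      ),
      indicators = list(
        mnm_ratio_per_1000 = report$mnm_ratio_per_1000[i],
        smo_ratio_per_1000 = report$smo_ratio_per_1000[i],
        mortality_index_pct = report$mortality_index_pct[i],
        mnm_to_md_ratio = report$mnm_to_md_ratio[i]
      ),
      presentation = list(
        mnm_ratio_per_1000 = pres$mnm_ratio_per_1000[i],
        smo_ratio_per_1000 = pres$smo_ratio_per_1000[i],
        mortality_index_pct = pres$mortality_index_pct[i],
        mnm_to_md_ratio = pres$mnm_to_md_ratio[i]
      )
    )
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full surveillance pipeline
#'
#' Ties the stages together: obtain a cohort (from a CSV file or by
#' simulation), classify it under the requested criteria sets, and write
#' per-record classifications, per-set indicator reports, the
#' cross-criteria comparison table, and the transfusion curve into an
#' output directory. Deterministic given the same inputs and seed.
#'
#' @param config a list with elements:
#'   * `input`: path to a cohort CSV, or `NULL` to simulate;
#'   * `live_births`: mandatory with a CSV input;
#'   * `spec`: an [cohort_spec()] (used when `input` is `NULL`);
#'   * `criteria`: character vector of set ids (default: all seven);
#'   * `out_dir`: output directory (created if needed).
#' @return invisible list of written artifact paths.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  ids <- config$criteria %||% sort(setdiff(builtin_set_ids(), "pltc_screen"))
  bad <- setdiff(ids, builtin_set_ids())
  if (length(bad)) {
    stop("configuration error: unknown criteria set id(s): ",
         paste(bad, collapse = ", "))
  }
  sets <- lapply(ids, criteria_set)
  if (!is.null(config$input)) {
    if (is.null(config$live_births)) {
      stop("configuration error: live_births is mandatory for a cohort file (the denominator is not the cohort size)")
    }
    cohort <- read_cohort(config$input, live_births = config$live_births)
  } else {
    spec <- config$spec %||% cohort_spec()
    cohort <- generate_cohort(spec)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  all_results <- list()
  for (cs in sets) {
    res <- classify_cohort(cohort, cs)
    all_results[[cs$set_id]] <- res
    p <- file.path(out_dir, paste0("classification_", cs$set_id, ".csv"))
    utils::write.csv(res, p, row.names = FALSE, quote = FALSE)
    pj <- file.path(out_dir, paste0("report_", cs$set_id, ".json"))
    write_report_json(compute_report(res, live_births = live_births(cohort),
                                     set_id = cs$set_id), pj)
    paths[[paste0("classification_", cs$set_id)]] <- p
    paths[[paste0("report_", cs$set_id)]] <- pj
  }
  comparison <- compare_criteria(cohort, sets)
  p_cmp <- file.path(out_dir, "comparison.csv")
  utils::write.csv(comparison, p_cmp, row.names = FALSE, quote = FALSE)
  paths$comparison <- p_cmp
  curve <- transfusion_curve(cohort, sets)
  p_curve <- file.path(out_dir, "transfusion_curve.csv")
  utils::write.csv(curve, p_curve, row.names = FALSE, quote = FALSE)
  paths$transfusion_curve <- p_curve
  prov <- list(seed = if (is.null(config$input)) (config$spec %||% cohort_spec())$seed else NULL,
               input = config$input, criteria = ids,
               live_births = live_births(cohort),
               n_records = nrow(cohort),
               package_version = as.character(utils::packageVersion("mnmtool")))
  p_prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, p_prov, auto_unbox = TRUE, null = "null", pretty = TRUE)
  paths$provenance <- p_prov
  invisible(paths)
}
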