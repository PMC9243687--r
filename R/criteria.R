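#' Criteria sets
#'
#' A criteria set is a named collection of declarative predicates with a
#' combination rule. Seven sets are shipped (WHO 2011, Mantel 1998,
#' Waterstone 2001, Roberts 2008, Indian national 2014, Global Network
#' 2016, CDC 2017) plus the WHO potentially-life-threatening-condition
#' screen. Sets are YAML documents; user-supplied YAML in the same grammar
#' defines custom sets.
#'
#' The expression grammar is:
#' * `{flag: token}` — flag present;
#' * `{measurement: token, cmp: "<|<=|>|>=", value: x}` — threshold on an
#'   observed measurement (a missing measurement never satisfies it);
#' * `{measurement: token, outside: [low, high]}` — true when the value is
#'   `> high` or `< low`;
#' * `{any_of: [...]}` / `{all_of: [...]}` — Boolean combinations.
#'
#' @param set_id one of the built-in set ids (see [builtin_set_ids()]).
#' @return A list of class `mnm_criteria` with elements `set_id`, `label`,
#'   `combinator` (`any_one` or `indian_sections`) and `predicates` (a list
#'   of predicates, each with `predicate_id`, `category`, optional
#'   `indian_section`, optional `pltc_category`, and `expression`).
#' @export
criteria_set <- function(set_id) {
  set_id <- match.arg(set_id, builtin_set_ids())
  if (is.null(.mnm_env$criteria)) .mnm_env$criteria <- list()
  if (!is.null(.mnm_env$criteria[[set_id]])) return(.mnm_env$criteria[[set_id]])
  cs <- load_criteria(mnm_extdata("criteria", paste0(set_id, ".yaml")))
  if (!identical(cs$set_id, set_id)) {
    stop("criteria file for '", set_id, "' declares set_id '", cs$set_id, "'")
  }
  if (set_id == "who_2011") {
    s <- criteria_summary(cs)
    if (s$n_predicates != 25 || s$n_clinical != 12 ||
        s$n_laboratory != 7 || s$n_management != 6) {
      stop("who_2011 must carry exactly 25 severity indicators ",
           "(12 clinical / 7 laboratory / 6 management)")
    }
  }
  if (cs$combinator == "indian_sections" && set_id != "indian_2014") {
    stop("the indian_sections combinator is reserved for indian_2014")
  }
  .mnm_env$criteria[[set_id]] <- cs
  cs
}

#' @rdname criteria_set
#' @export
builtin_set_ids <- function() {
  c("who_2011", "mantel_1998", "waterstone_2001", "roberts_2008",
    "indian_2014", "global_network_2016", "cdc_2017", "pltc_screen")
}

#' @rdname criteria_set
#' @return `comparison_sets()` returns the seven near-miss criteria sets
#'   (everything but the PLTC screen), as a named list ordered by set id.
#' @export
comparison_sets <- function() {
  ids <- sort(setdiff(builtin_set_ids(), "pltc_screen"))
  stats::setNames(lapply(ids, criteria_set), ids)
}

#' Load and validate a criteria set from YAML
#'
#' @param path path to a criteria YAML document.
#' @param vocabulary vocabulary data frame used to validate token
#'   references.
#' @return an `mnm_criteria` object.
#' @export
load_criteria <- function(path, vocabulary = mnm_vocabulary()) {
  doc <- yaml::read_yaml(path)
  validate_criteria(doc, vocabulary)
}

#' @rdname load_criteria
#' @param criteria a criteria set given as an R list in the YAML structure.
#' @export
validate_criteria <- function(criteria, vocabulary = mnm_vocabulary()) {
  conf_stop <- function(...) stop("criteria configuration error: ", ..., call. = FALSE)
  if (is.null(criteria$set_id)) conf_stop("missing set_id")
  combinator <- criteria$combinator %||% "any_one"
  if (!combinator %in% c("any_one", "indian_sections")) {
    conf_stop("unknown combinator '", combinator, "' in set '", criteria$set_id, "'")
  }
  preds <- criteria$predicates
  if (is.null(preds) || length(preds) == 0) conf_stop("set '", criteria$set_id, "' has no predicates")
  ids <- vapply(preds, function(p) p$predicate_id %||% NA_character_, character(1))
  if (anyNA(ids)) conf_stop("every predicate needs a predicate_id (set '", criteria$set_id, "')")
  if (anyDuplicated(ids)) {
    conf_stop("duplicate predicate_id in set '", criteria$set_id, "': ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (p in preds) {
    cat_ <- p$category %||% NA_character_
    if (!isTRUE(cat_ %in% c("clinical", "laboratory", "management"))) {
      conf_stop("predicate '", p$predicate_id, "' has invalid category '", cat_, "'")
    }
    if (combinator == "indian_sections") {
      sec <- p$indian_section %||% NA_character_
      if (!isTRUE(sec %in% c("clinical_finding", "investigation", "intervention", "collapse"))) {
        conf_stop("indian_sections requires an indian_section on every predicate; '",
                  p$predicate_id, "' has '", sec, "'")
      }
    }
    validate_expression(p$expression, p$predicate_id, vocabulary)
  }
  structure(list(set_id = criteria$set_id,
                 label = criteria$label %||% criteria$set_id,
                 combinator = combinator,
                 predicates = preds),
            class = "mnm_criteria")
}

# Recursive structural + vocabulary check of one expression.
validate_expression <- function(expr, predicate_id, vocabulary) {
  conf_stop <- function(...) {
    stop("criteria configuration error in predicate '", predicate_id, "': ", ...,
         call. = FALSE)
  }
  if (!is.list(expr)) conf_stop("expression must be a mapping")
  if (!is.null(expr$flag)) {
    if (!expr$flag %in% flag_tokens(vocabulary)) {
      conf_stop("unknown flag token '", expr$flag, "'")
    }
    return(invisible(TRUE))
  }
  if (!is.null(expr$measurement)) {
    if (!expr$measurement %in% measurement_tokens(vocabulary)) {
      conf_stop("unknown measurement token '", expr$measurement, "'")
    }
    if (!is.null(expr$outside)) {
      rng <- unlist(expr$outside)
      if (length(rng) != 2 || !all(is.finite(rng)) || rng[1] >= rng[2]) {
        conf_stop("outside range must be [low, high] with low < high")
      }
      return(invisible(TRUE))
    }
    if (is.null(expr$cmp) || !expr$cmp %in% c("<", "<=", ">", ">=")) {
      conf_stop("threshold comparator must be one of <, <=, >, >=")
    }
    if (is.null(expr$value) || !is.finite(expr$value)) {
      conf_stop("threshold value must be finite")
    }
    return(invisible(TRUE))
  }
  sub <- expr$any_of %||% expr$all_of
  if (!is.null(sub)) {
    if (length(sub) == 0) conf_stop("any_of/all_of must not be empty")
    for (e in sub) validate_expression(e, predicate_id, vocabulary)
    return(invisible(TRUE))
  }
  conf_stop("expression is none of flag / threshold / outside / any_of / all_of")
}

#' @rdname criteria_set
#' @param criteria an `mnm_criteria` object.
#' @return `criteria_summary()` returns a one-row data frame with the set
#'   id, combinator, and predicate counts by category.
#' @export
criteria_summary <- function(criteria) {
  cats <- vapply(criteria$predicates, function(p) p$category, character(1))
  data.frame(set_id = criteria$set_id,
             combinator = criteria$combinator,
             n_predicates = length(criteria$predicates),
             n_clinical = sum(cats == "clinical"),
             n_laboratory = sum(cats == "laboratory"),
             n_management = sum(cats == "management"),
             stringsAsFactors = FALSE)
}
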