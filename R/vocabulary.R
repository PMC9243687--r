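#' Indicator vocabulary
#'
#' The controlled vocabulary of patient-record indicators that every criteria
#' set evaluates against: clinical condition flags, management flags, and
#' numeric measurements (each with a canonical unit). The vocabulary is
#' shipped as a versioned YAML document under `inst/extdata/vocabulary.yaml`
#' and cached after first load.
#'
#' @param path optional path to an alternative vocabulary YAML.
#' @return A data frame with one row per token and columns `token`, `kind`
#'   (`condition_flag`, `management_flag`, or `measurement`), `unit` (`NA`
#'   for flags), `label` and `source`.
#' @export
mnm_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.mnm_env$vocabulary)) return(.mnm_env$vocabulary)
    path <- mnm_extdata("vocabulary.yaml")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  doc <- yaml::read_yaml(path)
  vocab <- do.call(rbind, lapply(doc$tokens, function(tk) {
    data.frame(
      token = tk$token,
      kind = tk$kind,
      unit = tk$unit %||% NA_character_,
      label = tk$label,
      source = tk$source %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(vocab$token)) {
    stop("vocabulary contains duplicate tokens: ",
         paste(unique(vocab$token[duplicated(vocab$token)]), collapse = ", "))
  }
  bad_kind <- setdiff(vocab$kind, c("condition_flag", "management_flag", "measurement"))
  if (length(bad_kind)) stop("unknown vocabulary kind(s): ", paste(bad_kind, collapse = ", "))
  if (any(vocab$kind == "measurement" & is.na(vocab$unit))) {
    stop("measurement tokens must declare a unit")
  }
  if (any(vocab$kind != "measurement" & !is.na(vocab$unit))) {
    stop("flag tokens must not declare a unit")
  }
  attr(vocab, "version") <- doc$version
  if (cache) .mnm_env$vocabulary <- vocab
  vocab
}

#' @rdname mnm_vocabulary
#' @param vocabulary a vocabulary data frame from [mnm_vocabulary()].
#' @export
flag_tokens <- function(vocabulary = mnm_vocabulary()) {
  vocabulary$token[vocabulary$kind %in% c("condition_flag", "management_flag")]
}

#' @rdname mnm_vocabulary
#' @export
measurement_tokens <- function(vocabulary = mnm_vocabulary()) {
  vocabulary$token[vocabulary$kind == "measurement"]
}

pltc_categories <- c("haemorrhage", "infection", "hypertensive", "medical", "labour_related")
timing_levels <- c("antenatal_t1", "antenatal_t2", "antenatal_t3",
                   "intrapartum", "postpartum", "post_abortion")
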