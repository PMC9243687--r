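`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Presentation rounding used for reported indicators. Unlike [base::round()]
#' (banker's rounding), halves round away from zero, which is the convention
#' used in clinical surveillance reports (e.g. 15.05 -> 15.1).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small guard against representation error, e.g. 8.85 stored as 8.84999...
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Convert a laboratory value from µmol/L to mg/dL
#'
#' Thresholds are stored canonically in mg/dL; values reported in µmol/L are
#' converted at ingest. Molar masses give creatinine ÷ 88.4 and
#' bilirubin ÷ 17.1.
#'
#' @param value numeric vector in µmol/L.
#' @param analyte `"creatinine"` or `"bilirubin"`.
#' @return numeric vector in mg/dL.
#' @export
umol_to_mg_dl <- function(value, analyte = c("creatinine", "bilirubin")) {
  analyte <- match.arg(analyte)
  value / switch(analyte, creatinine = 88.4, bilirubin = 17.1)
}

.mnm_env <- new.env(parent = emptyenv())

mnm_extdata <- function(...) {
  system.file("extdata", ..., package = "mnmtool", mustWork = TRUE)
}
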