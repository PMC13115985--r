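#' Deterministic classification rules
#'
#' The study's fixed clinical rules, applied per patient: binarising the
#' circulating endometrial cell (CEC) count, binarising serum CA125,
#' assigning dysmenorrhea severity strata from the visual analogue scale
#' (VAS), classifying lesion activity, and pooling menstrual-cycle phases.
#' All are vectorised and total on their stated domains.
#'
#' @name classification-rules
NULL

#' Binarise a CEC count
#'
#' A sample is CEC-positive when at least one circulating endometrial cell
#' is detected per 6 mL of peripheral blood.
#'
#' @param cec_count Non-negative integer vector of cells per 6 mL.
#' @return Logical vector, `TRUE` for positive. `NA` counts stay `NA`.
#' @examples
#' binarize_cec(c(0, 1, 7))
#' @export
binarize_cec <- function(cec_count) {
  bad <- !is.na(cec_count) & (cec_count < 0 | cec_count != floor(cec_count))
  if (any(bad)) {
    abort(sprintf(
      "`cec_count` must be a non-negative integer; offending value(s): %s",
      paste(utils::head(cec_count[bad], 3), collapse = ", ")
    ))
  }
  cec_count >= 1
}

#' Binarise a serum CA125 value
#'
#' @param value Non-negative numeric vector, U/mL.
#' @param threshold Positivity cut-off in U/mL. Defaults to the
#'   conventional clinical cut-off of 35 U/mL; positivity is inclusive
#'   (`value >= threshold`).
#' @return Logical vector. `NA` values stay `NA`.
#' @export
binarize_ca125 <- function(value, threshold = 35) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number (U/mL).")
  }
  if (any(!is.na(value) & value < 0)) {
    abort("CA125 values must be non-negative (U/mL).")
  }
  value >= threshold
}

round_half_up <- function(x) floor(x + 0.5)

#' Dysmenorrhea severity stratum from a VAS pain score
#'
#' VAS 0 maps to `none`, 1-3 to `mild`, 4-6 to `moderate`, and 7-10 to
#' `severe`. Fractional scores are rounded half-up to the nearest integer
#' before lookup (the strata are defined on the clinical 0-10 integer
#' scale).
#'
#' @param vas Numeric vector in \[0, 10\].
#' @return Factor with levels `none`, `mild`, `moderate`, `severe`.
#' @examples
#' vas_stratum(c(0, 2, 5, 8))
#' @export
vas_stratum <- function(vas) {
  if (any(!is.na(vas) & (vas < 0 | vas > 10))) {
    abort("`vas` must lie in [0, 10].")
  }
  v <- round_half_up(vas)
  out <- dplyr::case_when(
    v == 0 ~ "none",
    v <= 3 ~ "mild",
    v <= 6 ~ "moderate",
    v <= 10 ~ "severe"
  )
  factor(out, levels = c("none", "mild", "moderate", "severe"))
}

#' Classify lesion activity
#'
#' Active endometriosis is defined as dysmenorrhea that worsened markedly
#' over the preceding six months together with moderate-to-severe pain.
#' Two readings of "moderate-to-severe" are supported: a strict VAS >= 6
#' cut (the default) or membership of the moderate/severe VAS strata
#' (VAS >= 4 after rounding).
#'
#' @param worsened_6mo Logical vector: marked worsening over six months.
#' @param vas Numeric vector in \[0, 10\].
#' @param rule `"vas_ge_6"` (default) or `"moderate_to_severe"`.
#' @return Factor with levels `active`, `dormant`.
#' @export
classify_activity <- function(worsened_6mo, vas,
                              rule = c("vas_ge_6", "moderate_to_severe")) {
  rule <- match.arg(rule)
  pain <- switch(rule,
    vas_ge_6 = vas >= 6,
    moderate_to_severe = vas_stratum(vas) %in% c("moderate", "severe")
  )
  factor(ifelse(worsened_6mo & pain, "active", "dormant"),
         levels = c("active", "dormant"))
}

#' Pool menstrual-cycle phases
#'
#' Menstrual and proliferative phases are pooled into a single stratum
#' (their CEC levels are comparable and the menstrual phase alone is too
#' small to analyse); the secretory phase stands alone.
#'
#' @param phase Character or factor vector with values `menstrual`,
#'   `proliferative`, `secretory`.
#' @return Factor with levels `prolif_menstrual`, `secretory`.
#' @export
pool_phase <- function(phase) {
  phase <- as.character(phase)
  known <- phase %in% c("menstrual", "proliferative", "secretory") | is.na(phase)
  if (!all(known)) {
    abort(sprintf("Unknown phase value(s): %s",
                  paste(unique(phase[!known]), collapse = ", ")))
  }
  out <- ifelse(phase == "secretory", "secretory", "prolif_menstrual")
  factor(out, levels = c("prolif_menstrual", "secretory"))
}
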