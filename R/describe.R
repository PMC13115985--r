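#' Descriptive layer: detection rates and stratified summaries
#'
#' Plain arithmetic on the cohort: positivity rates with mean counts
#' (zeros included, so a rate always pairs with the mean over the whole
#' group), stratified breakdowns, and cell-size subtype proportions.
#'
#' @name descriptive-stats
NULL

#' CEC detection rate and mean count for a group
#'
#' @param data A cohort subset (tibble) with `cec_count`.
#' @param positive Optional logical vector overriding the default
#'   positivity rule (at least one cell per 6 mL).
#' @return One-row tibble: `n`, `n_positive`, `detection_rate`,
#'   `mean_count`, `sd_count`.
#' @export
detection_rate <- function(data, positive = NULL) {
  if (nrow(data) == 0) {
    warn("Empty group: detection rate undefined.")
    return(tibble::tibble(n = 0L, n_positive = 0L,
                          detection_rate = NA_real_,
                          mean_count = NA_real_, sd_count = NA_real_))
  }
  pos <- positive %||% binarize_cec(data$cec_count)
  tibble::tibble(
    n = nrow(data),
    n_positive = sum(pos, na.rm = TRUE),
    detection_rate = sum(pos, na.rm = TRUE) / nrow(data),
    mean_count = mean(data$cec_count),
    sd_count = sd(data$cec_count)
  )
}

#' Stratified detection summary
#'
#' One [detection_rate()] row per stratum. Strata must partition the
#' cohort: a missing stratum label is an error, and the per-stratum sizes
#' always sum to the cohort size.
#'
#' @param cohort A cohort tibble.
#' @param strata Bare column name or an expression evaluated in the
#'   cohort (e.g. `vas_stratum(vas)`), giving one label per patient.
#' @return Tibble with a leading `stratum` column, one row per level.
#' @export
stratified_summary <- function(cohort, strata) {
  labels <- dplyr::pull(dplyr::mutate(cohort, .s = {{ strata }}), ".s")
  if (anyNA(labels)) {
    abort("Strata must partition the cohort: missing stratum label(s) found.")
  }
  lev <- if (is.factor(labels)) levels(labels) else unique(labels)
  purrr::map_dfr(lev, function(l) {
    dplyr::bind_cols(tibble::tibble(stratum = l),
                     detection_rate(cohort[labels == l, , drop = FALSE]))
  })
}

#' Pooled small-cell proportion by group
#'
#' Proportion of detected cells that are small (< 5 um), pooled over all
#' cells in each group.
#'
#' @param data Tibble with `small_count` and `large_count` per patient.
#' @param group Bare column name for grouping (optional; one pooled row
#'   when omitted).
#' @return Tibble: `group`, `cells_small`, `cells_large`,
#'   `prop_small` (`NA`, flagged by warning, for a group with no cells).
#' @export
subtype_proportions <- function(data, group = NULL) {
  if (any(data$small_count < 0 | data$large_count < 0, na.rm = TRUE)) {
    abort("Subtype counts must be non-negative.")
  }
  g <- rlang::enquo(group)
  labels <- if (rlang::quo_is_null(g)) rep("all", nrow(data))
            else dplyr::pull(dplyr::mutate(data, .g = !!g), ".g")
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(labels,
                                   small = data$small_count,
                                   large = data$large_count), labels),
    cells_small = sum(.data$small), cells_large = sum(.data$large),
    .groups = "drop")
  out <- dplyr::rename(out, group = "labels")
  total <- out$cells_small + out$cells_large
  if (any(total == 0)) {
    warn("Group(s) with zero detected cells: proportion undefined.")
  }
  dplyr::mutate(out, prop_small = ifelse(total == 0, NA_real_,
                                         .data$cells_small / total))
}

#' Render a detection summary in the conventional text style
#'
#' Formats rates as `"64.0% (55/86)"`.
#'
#' @param summary Output of [detection_rate()] or [stratified_summary()].
#' @return Character vector, one entry per row.
#' @export
format_detection <- function(summary) {
  sprintf("%.1f%% (%d/%d)", 100 * summary$detection_rate,
          summary$n_positive, summary$n)
}
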