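#' Patient-level cohort tables
#'
#' A cohort is a tibble with one row per participant and a fixed column
#' vocabulary:
#'
#' * `patient_id` — opaque unique identifier (character).
#' * `lap_result` — laparoscopy result, logical or `NA` (not operated).
#' * `cec_count` — circulating endometrial cells per 6 mL, non-negative
#'   integer.
#' * `ca125_value` — serum CA125 in U/mL (may be `NA`).
#' * `ca125_positive` — logical positivity call (may be `NA`).
#' * `vas` — visual analogue scale pain score in \[0, 10\].
#' * `phase` — `menstrual`, `proliferative`, or `secretory`.
#' * `worsened_6mo` — dysmenorrhea worsened markedly over six months.
#' * `treated` — preoperative medical treatment.
#' * `group_label` — `EM_surgical`, `EM_clinical`, `control_benign`, or
#'   `control_malignant`.
#' * `adenomyosis` — concomitant adenomyosis (logical).
#' * `true_status` — latent disease status; present only in synthetic
#'   cohorts.
#'
#' Only `patient_id`, `cec_count`, `vas`, and `phase` are mandatory;
#' missing test results are carried as explicit `NA` and handled pairwise
#' by the likelihood, so clinically diagnosed patients without surgery can
#' be scored.
#'
#' @name cohort
NULL

cohort_phases <- c("menstrual", "proliferative", "secretory")
cohort_groups <- c("EM_surgical", "EM_clinical", "control_benign",
                   "control_malignant")

mandatory_cols <- c("patient_id", "cec_count", "vas", "phase")
optional_cols <- c("lap_result", "ca125_value", "ca125_positive",
                   "worsened_6mo", "treated", "group_label", "adenomyosis",
                   "true_status")

#' Validate a cohort table
#'
#' Checks the column contract and row-level invariants (counts integral and
#' non-negative, VAS within \[0, 10\], phases known, CA125 positivity
#' consistent with the value at the stated threshold, unique patient ids).
#' Violations are reported with their row numbers.
#'
#' @param data A data frame of patient records.
#' @param provenance `"observed"` or `"synthetic"`. Synthetic cohorts must
#'   carry a `true_status` column; observed cohorts must not.
#' @param ca125_threshold Threshold used for the consistency check, U/mL.
#' @return The validated cohort as a tibble (invisibly classed
#'   `cec_cohort`), with `provenance` stored as an attribute.
#' @export
validate_cohort <- function(data, provenance = c("observed", "synthetic"),
                            ca125_threshold = 35) {
  provenance <- match.arg(provenance)
  data <- tibble::as_tibble(data)

  missing_cols <- setdiff(mandatory_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("Cohort must contain at least one record.")
  if (!is.numeric(data$vas)) {
    abort("`vas` must be numeric (VAS score in [0, 10]).")
  }

  has_truth <- "true_status" %in% names(data) && !all(is.na(data$true_status))
  if (provenance == "synthetic" && !has_truth) {
    abort("Synthetic cohorts must carry a `true_status` column.")
  }
  if (provenance == "observed" && has_truth) {
    abort("Observed cohorts must not carry `true_status`; did you mean provenance = \"synthetic\"?")
  }

  problems <- character(0)
  bad_rows <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf(
        "%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
        paste(utils::head(rows, 5), collapse = ", ")))
    }
  }

  bad_rows(is.na(data$patient_id) | data$patient_id == "", "empty patient_id")
  bad_rows(duplicated(data$patient_id), "duplicate patient_id")
  bad_rows(!is.na(data$cec_count) &
             (data$cec_count < 0 | data$cec_count != floor(data$cec_count)),
           "cec_count not a non-negative integer")
  bad_rows(!is.na(data$vas) & (data$vas < 0 | data$vas > 10),
           "vas outside [0, 10]")
  bad_rows(!data$phase %in% cohort_phases & !is.na(data$phase),
           "unknown phase")
  if ("group_label" %in% names(data)) {
    bad_rows(!data$group_label %in% cohort_groups & !is.na(data$group_label),
             "unknown group_label")
  }
  if (all(c("ca125_value", "ca125_positive") %in% names(data))) {
    both <- !is.na(data$ca125_value) & !is.na(data$ca125_positive)
    bad_rows(both & (data$ca125_positive !=
                       (data$ca125_value >= ca125_threshold)),
             sprintf("ca125_positive inconsistent with ca125_value at %g U/mL",
                     ca125_threshold))
  }
  if ("ca125_value" %in% names(data)) {
    bad_rows(!is.na(data$ca125_value) & data$ca125_value < 0,
             "negative ca125_value")
  }

  if (length(problems) > 0) {
    abort(c("Cohort validation failed:", setNames(problems, rep("x", length(problems)))))
  }

  class(data) <- unique(c("cec_cohort", class(data)))
  attr(data, "provenance") <- provenance
  data
}

#' Read a cohort CSV
#'
#' Reads a UTF-8 comma-separated file with a header row and one row per
#' patient, optionally renaming file columns to the canonical vocabulary
#' through a schema mapping, and validates the result.
#'
#' @param path Path to the CSV file.
#' @param schema Optional column mapping: a named character vector or list
#'   (canonical name -> file column name), or the path to a JSON file
#'   holding such a mapping.
#' @inheritParams validate_cohort
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, schema = NULL,
                        provenance = c("observed", "synthetic"),
                        ca125_threshold = 35) {
  provenance <- match.arg(provenance)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))

  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (!is.null(schema)) {
    schema <- unlist(schema)
    absent <- setdiff(unname(schema), names(data))
    if (length(absent) > 0) {
      abort(sprintf("Schema maps to column(s) absent from the file: %s",
                    paste(absent, collapse = ", ")))
    }
    data <- dplyr::rename(data, !!!schema)
  }
  for (col in intersect(c("lap_result", "ca125_positive", "worsened_6mo",
                          "treated", "adenomyosis", "true_status"),
                        names(data))) {
    data[[col]] <- as.logical(data[[col]])
  }
  if ("patient_id" %in% names(data)) {
    data$patient_id <- as.character(data$patient_id)
  }
  out <- validate_cohort(data, provenance = provenance,
                         ca125_threshold = ca125_threshold)
  for (col in intersect(c("cec_count", "small_count", "large_count"),
                        names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: all fields round-trip exactly (CA125 values
#' are stored to two decimals by the generator, so no precision is lost).
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Build a binary test panel from a cohort
#'
#' Extracts the three study tests as an n-by-K 0/1 matrix with `NA` for
#' missing results: laparoscopy from `lap_result`, CEC positivity from the
#' count (at least one cell per 6 mL), and CA125 from `ca125_positive`
#' where available, otherwise by thresholding `ca125_value`.
#'
#' @param cohort A cohort tibble.
#' @param tests Character vector of test names to include, a subset of
#'   `c("laparoscopy", "CEC", "CA125")`, in panel order.
#' @param ca125_threshold CA125 cut-off in U/mL when positivity must be
#'   derived from the value.
#' @return Integer matrix (rows = patients, columns = `tests`), rownames
#'   set to `patient_id`.
#' @export
as_test_panel <- function(cohort, tests = c("laparoscopy", "CEC", "CA125"),
                          ca125_threshold = 35) {
  tests <- match.arg(tests, several.ok = TRUE)
  cols <- lapply(tests, function(t) {
    switch(t,
      laparoscopy = as.integer(cohort$lap_result),
      CEC = as.integer(binarize_cec(cohort$cec_count)),
      CA125 = {
        pos <- if ("ca125_positive" %in% names(cohort)) {
          cohort$ca125_positive
        } else {
          NA
        }
        val_pos <- if ("ca125_value" %in% names(cohort)) {
          binarize_ca125(cohort$ca125_value, ca125_threshold)
        } else {
          NA
        }
        as.integer(dplyr::coalesce(pos, val_pos))
      }
    )
  })
  panel <- do.call(cbind, cols)
  colnames(panel) <- tests
  rownames(panel) <- cohort$patient_id
  panel
}
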