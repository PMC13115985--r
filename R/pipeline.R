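#' End-to-end pipeline commands
#'
#' Thin orchestration over the analysis modules, suitable for scripting:
#' each command reads/writes plain CSV/JSON, takes every seed explicitly,
#' logs its configuration hash and run metadata to stderr, and is
#' bit-reproducible under a fixed configuration. The shell entry point
#' `inst/cli/cecdx.R` dispatches to these functions.
#'
#' @name pipeline
NULL

log_msg <- function(...) message(sprintf(...))

#' Simulate a cohort to disk
#'
#' Writes `cohort.csv` plus a `truth.json` sidecar holding the preset
#' name, seed, configuration hash, and the realised latent prevalence.
#'
#' @param preset Scenario preset name (see [scenario_preset()]).
#' @param out_dir Output directory (created if needed).
#' @param n Cohort size; `NULL` keeps the preset's stratum size.
#' @param stratum Stratum within the preset, where applicable.
#' @param seed Integer seed.
#' @param subtypes Also draw small/large cell subtype counts.
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(preset, out_dir, n = NULL, stratum = NULL, seed,
                         subtypes = FALSE) {
  if (missing(seed)) abort("`seed` is mandatory.")
  config <- scenario_preset(preset, stratum = stratum, n = n)
  cohort <- simulate_cohort(config, seed = seed)
  if (subtypes) cohort <- simulate_subtypes(cohort, config, seed = seed + 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort_path <- file.path(out_dir, "cohort.csv")
  truth_path <- file.path(out_dir, "truth.json")
  write_cohort(cohort, cohort_path)
  jsonlite::write_json(list(
    preset = preset, stratum = stratum, n = nrow(cohort), seed = seed,
    config_hash = attr(cohort, "config_hash"),
    realised_prevalence = mean(cohort$true_status)
  ), truth_path, auto_unbox = TRUE, digits = NA, null = "null")

  log_msg("simulate: preset=%s n=%d seed=%d hash=%s", preset, nrow(cohort),
          seed, attr(cohort, "config_hash"))
  invisible(c(cohort = cohort_path, truth = truth_path))
}

#' Fit the latent class model and write the accuracy table
#'
#' Reads a cohort CSV, fits the constrained model (optionally per
#' stratum), and writes `accuracy.csv`, `accuracy.json`, and `fit.json`.
#'
#' @param cohort_csv Path to a cohort CSV ([read_cohort()] format).
#' @param out_dir Output directory.
#' @param strata `"none"`, `"vas"`, `"activity"`, or `"phase"`.
#' @param fix_lap_specificity Keep laparoscopy specificity fixed at 1.
#' @param B,M Bootstrap replicates and imputations.
#' @param seed Integer seed.
#' @param provenance Cohort provenance for validation.
#' @return Named character vector of the files written, invisibly.
#' @export
run_fit <- function(cohort_csv, out_dir, strata = "none",
                    fix_lap_specificity = TRUE, B = 1000, M = 50, seed,
                    provenance = "synthetic") {
  if (missing(seed)) abort("`seed` is mandatory.")
  cohort <- read_cohort(cohort_csv, provenance = provenance)
  constraints <- if (fix_lap_specificity) study_constraints()
                 else lca_constraints(anchor = "laparoscopy")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  table <- switch(strata,
    none = accuracy_report(cohort, NULL, constraints = constraints,
                           M = M, B = B, seed = seed),
    vas = accuracy_report(cohort, vas_stratum(vas),
                          constraints = constraints, M = M, B = B,
                          seed = seed),
    activity = accuracy_report(cohort,
                               classify_activity(worsened_6mo, vas),
                               constraints = constraints, M = M, B = B,
                               seed = seed),
    phase = accuracy_report(cohort, pool_phase(phase),
                            constraints = constraints, M = M, B = B,
                            seed = seed),
    abort(sprintf("Unknown strata choice '%s'.", strata))
  )

  fit <- fit_lca(as_test_panel(cohort), constraints = constraints,
                 seed = seed)
  csv_path <- file.path(out_dir, "accuracy.csv")
  json_path <- file.path(out_dir, "accuracy.json")
  fit_path <- file.path(out_dir, "fit.json")
  write_accuracy(table, csv_path, json_path)
  write_fit_json(fit, fit_path)

  log_msg("fit: n=%d strata=%s seed=%d restarts=%d loglik=%.4f",
          nrow(cohort), strata, seed, fit$restarts_used, fit$loglik)
  invisible(c(accuracy_csv = csv_path, accuracy_json = json_path,
              fit = fit_path))
}

#' Fit accuracy curves per pooled phase stratum
#'
#' Writes one long-format curve CSV per pooled-phase stratum present in
#' the cohort.
#'
#' @inheritParams run_fit
#' @param bandwidth Kernel bandwidth (`NULL` = Silverman's rule).
#' @param grid_step VAS grid step over \[0, 10\].
#' @param B Bootstrap replicates for the bands (0 = none).
#' @return Named character vector of the files written, invisibly.
#' @export
run_curves <- function(cohort_csv, out_dir, bandwidth = NULL,
                       grid_step = 0.25, B = 200, seed,
                       fix_lap_specificity = TRUE,
                       provenance = "synthetic") {
  if (missing(seed)) abort("`seed` is mandatory.")
  cohort <- read_cohort(cohort_csv, provenance = provenance)
  constraints <- if (fix_lap_specificity) study_constraints()
                 else lca_constraints(anchor = "laparoscopy")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- seq(0, 10, by = grid_step)

  strata <- unique(as.character(pool_phase(cohort$phase)))
  paths <- character(0)
  for (s in strata) {
    curve <- fit_curve(cohort, stratum = s, grid = grid,
                       bandwidth = bandwidth, constraints = constraints,
                       B = B, seed = seed)
    path <- file.path(out_dir, sprintf("curve_%s.csv", s))
    write_curve(curve, path)
    paths[s] <- path
    log_msg("curves: stratum=%s points=%d bandwidth=%.3f seed=%d",
            s, length(grid), curve$bandwidth[1], seed)
  }
  invisible(paths)
}

#' Descriptive tables for a cohort
#'
#' Writes detection summaries overall, by group label, by dysmenorrhea
#' severity, by lesion activity, and by pooled phase, plus subtype
#' proportions when subtype counts are present.
#'
#' @inheritParams run_fit
#' @return Named character vector of the files written, invisibly.
#' @export
run_describe <- function(cohort_csv, out_dir, provenance = "synthetic") {
  cohort <- read_cohort(cohort_csv, provenance = provenance)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- list(
    overall = dplyr::bind_cols(tibble::tibble(stratum = "overall"),
                               detection_rate(cohort)),
    by_group = stratified_summary(cohort, group_label),
    by_vas = stratified_summary(cohort, vas_stratum(vas)),
    by_activity = stratified_summary(
      cohort, classify_activity(worsened_6mo, vas)),
    by_phase = stratified_summary(cohort, pool_phase(phase))
  )
  if (all(c("small_count", "large_count") %in% names(cohort))) {
    tables$subtypes <- subtype_proportions(cohort, group_label)
  }
  paths <- purrr::imap_chr(tables, function(t, nm) {
    path <- file.path(out_dir, sprintf("describe_%s.csv", nm))
    readr::write_csv(t, path, progress = FALSE)
    path
  })
  log_msg("describe: n=%d tables=%d", nrow(cohort), length(paths))
  invisible(paths)
}
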