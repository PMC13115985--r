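#' Pooled inference: imputation estimator and bootstrap intervals
#'
#' For overall and phase-only analyses the point estimates come from an
#' imputation scheme: latent disease status is drawn repeatedly from each
#' patient's posterior probability, each test is cross-tabulated against
#' the imputed statuses, and the draws are averaged. All confidence
#' intervals are percentile bootstrap over patients, refitting the model
#' (and re-imputing) within every replicate.
#'
#' @name pooled-inference
NULL

#' Imputation-based accuracy point estimates
#'
#' For m = 1..M, draws latent statuses `D_i ~ Bernoulli(gamma_i)` from the
#' fitted posterior responsibilities, computes every test's sensitivity
#' and specificity against `D` by cross-tabulation (missing results
#' excluded pairwise), and averages over the M draws. Draws in which one
#' class is empty leave their cells undefined; such cells are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param panel Test panel matrix (see [as_test_panel()]).
#' @param gamma Per-patient posterior disease probabilities, e.g.
#'   `fit$responsibilities` from [fit_lca()], or [posterior_from_curve()]
#'   for the covariate model (each patient's own VAS).
#' @param M Number of imputations (>= 2).
#' @param seed Integer seed.
#' @return Tibble: `test`, `sensitivity`, `specificity`, with attribute
#'   `n_skipped` (undefined cells across draws).
#' @export
impute_accuracy <- function(panel, gamma, M = 50, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (M < 2) abort("`M` must be at least 2.")
  stopifnot(length(gamma) == nrow(panel), all(gamma >= 0 & gamma <= 1))
  n <- nrow(panel)
  K <- ncol(panel)
  se_sum <- sp_sum <- se_cnt <- sp_cnt <- setNames(numeric(K), colnames(panel))
  d <- withr::with_seed(seed, {
    matrix(rbinom(n * M, 1, gamma), nrow = n, ncol = M)
  })
  for (k in seq_len(K)) {
    y <- panel[, k]
    obs <- !is.na(y)
    d_obs <- d[obs, , drop = FALSE]
    n_dis <- colSums(d_obs)
    n_hea <- sum(obs) - n_dis
    se_m <- as.numeric(crossprod(y[obs], d_obs)) / n_dis
    sp_m <- as.numeric(crossprod(1 - y[obs], 1 - d_obs)) / n_hea
    se_cnt[k] <- sum(n_dis > 0)
    sp_cnt[k] <- sum(n_hea > 0)
    se_sum[k] <- sum(se_m[n_dis > 0])
    sp_sum[k] <- sum(sp_m[n_hea > 0])
  }
  skipped <- sum(M - se_cnt) + sum(M - sp_cnt)
  if (skipped > 0) {
    inform(sprintf("%d undefined accuracy cell(s) skipped across %d imputations.",
                   skipped, M))
  }
  out <- tibble::tibble(
    test = colnames(panel),
    sensitivity = unname(ifelse(se_cnt > 0, se_sum / se_cnt, NA_real_)),
    specificity = unname(ifelse(sp_cnt > 0, sp_sum / sp_cnt, NA_real_))
  )
  attr(out, "n_skipped") <- skipped
  out
}

#' Posterior disease probability at each patient's own covariates
#'
#' Evaluates the covariate-varying model at every patient's VAS by linear
#' interpolation of the fitted curve parameters over the grid, then
#' applies Bayes' rule to the patient's test pattern.
#'
#' @param curve A `cec_curve` from [fit_curve()].
#' @param panel Test panel for the same patients.
#' @param vas Their VAS scores.
#' @return Posterior probability vector.
#' @export
posterior_from_curve <- function(curve, panel, vas) {
  interp <- function(param, test = NA_character_) {
    sub <- curve[curve$parameter == param &
                   (is.na(test) & is.na(curve$test) |
                      !is.na(test) & !is.na(curve$test) & curve$test == test) &
                   !curve$flagged, ]
    approx(sub$vas, sub$estimate, xout = vas, rule = 2)$y
  }
  n <- length(vas)
  prev <- interp("prevalence")
  l1 <- l0 <- rep(1, n)
  for (k in colnames(panel)) {
    se <- interp("sensitivity", k)
    fp <- 1 - interp("specificity", k)
    y <- panel[, k]
    obs <- !is.na(y)
    l1[obs] <- l1[obs] * ifelse(y[obs] == 1, se[obs], 1 - se[obs])
    l0[obs] <- l0[obs] * ifelse(y[obs] == 1, fp[obs], 1 - fp[obs])
  }
  mix <- prev * l1 + (1 - prev) * l0
  gamma <- prev * l1 / mix
  gamma[mix == 0] <- prev[mix == 0]
  gamma
}

#' Percentile bootstrap confidence intervals
#'
#' Resamples patients with replacement (within strata when
#' `stratified_by` is given), applies `estimator` to each replicate, and
#' returns per-term 2.5/97.5 percentile bounds. Replicates on which the
#' estimator errors are dropped and counted; more than 10% failures is an
#' error.
#'
#' @param data A data frame of patients (rows are the resampling unit).
#' @param estimator Function `data -> named numeric vector`.
#' @param B Number of bootstrap replicates (>= 100 for reported CIs).
#' @param stratified_by Optional column name: resampling is done within
#'   each level, preserving stratum sizes.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `term`, `lower`, `upper`, `b_ok` (replicates used).
#' @export
bootstrap_ci <- function(data, estimator, B = 1000, stratified_by = NULL,
                         seed, conf = 0.95) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (B < 100) {
    warn("B < 100: intervals are for exploration only, not reporting.")
  }
  n <- nrow(data)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- if (is.null(stratified_by)) {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(lapply(split(seq_len(n), data[[stratified_by]]), function(s) {
          s[sample.int(length(s), length(s), replace = TRUE)]
        }), use.names = FALSE)
      }
      tryCatch(estimator(data[idx, , drop = FALSE]),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > 0.10) {
    abort(sprintf("Estimator failed on %d of %d bootstrap replicates (> 10%%).",
                  sum(!ok), B))
  }
  if (sum(!ok) > 0) {
    inform(sprintf("%d of %d bootstrap replicates failed and were dropped.",
                   sum(!ok), B))
  }
  est <- do.call(rbind, draws[ok])
  alpha <- (1 - conf) / 2
  tibble::tibble(
    term = colnames(est),
    lower = unname(apply(est, 2, quantile, probs = alpha, na.rm = TRUE,
                         names = FALSE)),
    upper = unname(apply(est, 2, quantile, probs = 1 - alpha, na.rm = TRUE,
                         names = FALSE)),
    b_ok = unname(apply(est, 2, function(x) sum(!is.na(x))))
  )
}

fit_impute_point <- function(cohort, tests, constraints, M, seed,
                             n_restarts = 20) {
  panel <- as_test_panel(cohort, tests = tests)
  fit <- fit_lca(panel, constraints = constraints, seed = seed,
                 n_restarts = n_restarts)
  acc <- impute_accuracy(panel, fit$responsibilities, M = M, seed = seed + 1)
  list(fit = fit, accuracy = acc)
}

#' Accuracy table with bootstrap intervals, per stratum
#'
#' The study's table pipeline: within each stratum, fit the constrained
#' latent class model, form imputation-based point estimates, and attach
#' percentile bootstrap intervals (the model is refit and re-imputed on
#' every bootstrap replicate). Strata smaller than `min_n` are flagged and
#' reported without intervals.
#'
#' @param cohort A cohort tibble.
#' @param strata Optional bare column name (or character) giving the
#'   stratification; `NULL` analyses the whole cohort as one stratum.
#' @param tests Panel columns.
#' @param constraints [lca_constraints()] for the fits.
#' @param M Imputations per point estimate.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param min_n Minimum stratum size below which the column is flagged.
#' @return Tibble of class `accuracy_table`: `stratum`, `n`, `test`,
#'   `sensitivity`, `sens_lo`, `sens_hi`, `specificity`, `spec_lo`,
#'   `spec_hi`, `flagged`.
#' @export
accuracy_report <- function(cohort, strata = NULL,
                            tests = c("laparoscopy", "CEC", "CA125"),
                            constraints = study_constraints(),
                            M = 50, B = 1000, seed, min_n = 15) {
  if (missing(seed)) abort("`seed` is mandatory.")
  strata_quo <- rlang::enquo(strata)
  if (rlang::quo_is_null(strata_quo)) {
    groups <- list(overall = cohort)
  } else {
    labels <- dplyr::pull(dplyr::mutate(cohort, .s = !!strata_quo), ".s")
    groups <- split(cohort, labels)
  }

  out <- purrr::imap_dfr(groups, function(d, label) {
    if (nrow(d) < min_n) {
      warn(sprintf("Stratum '%s' has n = %d < %d; flagged, no intervals.",
                   label, nrow(d), min_n))
      return(tibble::tibble(
        stratum = label, n = nrow(d), test = tests,
        sensitivity = NA_real_, sens_lo = NA_real_, sens_hi = NA_real_,
        specificity = NA_real_, spec_lo = NA_real_, spec_hi = NA_real_,
        flagged = TRUE))
    }
    pt <- fit_impute_point(d, tests, constraints, M, seed)
    warm <- pt$fit$params
    ci <- bootstrap_ci(
      d,
      estimator = function(db) {
        panel <- as_test_panel(db, tests = tests)
        f <- tryCatch(
          fit_lca(panel, constraints = constraints, seed = seed,
                  init = warm),
          error = function(e) NULL)
        if (is.null(f)) stop("refit failed")
        acc <- impute_accuracy(panel, f$responsibilities, M = M,
                               seed = seed + 1)
        setNames(c(acc$sensitivity, acc$specificity),
                 c(paste0("se_", acc$test), paste0("sp_", acc$test)))
      },
      B = B, seed = seed + 2)
    tibble::tibble(
      stratum = label, n = nrow(d), test = pt$accuracy$test,
      sensitivity = pt$accuracy$sensitivity,
      sens_lo = ci$lower[match(paste0("se_", pt$accuracy$test), ci$term)],
      sens_hi = ci$upper[match(paste0("se_", pt$accuracy$test), ci$term)],
      specificity = pt$accuracy$specificity,
      spec_lo = ci$lower[match(paste0("sp_", pt$accuracy$test), ci$term)],
      spec_hi = ci$upper[match(paste0("sp_", pt$accuracy$test), ci$term)],
      flagged = FALSE)
  })
  class(out) <- unique(c("accuracy_table", class(out)))
  out
}

#' Render an accuracy table in the conventional text style
#'
#' Formats each cell as `"0.58 (0.50, 0.72)"`.
#'
#' @param table An `accuracy_table` tibble.
#' @param digits Decimal places.
#' @return Tibble: `stratum`, `test`, `sensitivity`, `specificity`
#'   (character cells).
#' @export
format_accuracy <- function(table, digits = 2) {
  cell <- function(p, lo, hi) {
    ifelse(is.na(p), "-", sprintf(
      sprintf("%%.%df (%%.%df, %%.%df)", digits, digits, digits),
      p, lo, hi))
  }
  tibble::tibble(
    stratum = table$stratum, test = table$test,
    sensitivity = cell(table$sensitivity, table$sens_lo, table$sens_hi),
    specificity = cell(table$specificity, table$spec_lo, table$spec_hi)
  )
}

#' Write an accuracy table to CSV and JSON
#'
#' @param table An `accuracy_table`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The paths, invisibly.
#' @export
write_accuracy <- function(table, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(table, csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(table, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(c(csv_path, json_path))
}
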