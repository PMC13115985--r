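#' Covariate-varying latent class estimation
#'
#' Prevalence and per-test accuracies as smooth functions of the VAS pain
#' score, estimated by kernel-weighted local-likelihood EM: at a target
#' score v0 every patient's likelihood contribution is weighted by
#' K((v_i - v0) / h) and the weighted EM is run to convergence
#' (local-constant / Nadaraya-Watson weighting). Menstrual-cycle phase is
#' handled by hard stratification into the two pooled strata, giving one
#' curve per stratum.
#'
#' @name covariate-lca
NULL

#' Kernel weights
#'
#' Kernels are scaled so K(0) = 1; the sum of weights is then an
#' effective sample size.
#'
#' @param vas Numeric vector of patient VAS scores.
#' @param v0 Target VAS value.
#' @param bandwidth Positive bandwidth in VAS units.
#' @param kernel `"gaussian"` or `"epanechnikov"`.
#' @return Non-negative weight vector.
#' @export
kernel_weights <- function(vas, v0, bandwidth,
                           kernel = c("gaussian", "epanechnikov")) {
  kernel <- match.arg(kernel)
  if (bandwidth <= 0) abort("`bandwidth` must be positive.")
  u <- (vas - v0) / bandwidth
  switch(kernel,
    gaussian = exp(-u^2 / 2),
    epanechnikov = pmax(1 - u^2, 0)
  )
}

#' Local latent class fit at one VAS value
#'
#' Runs the constrained EM of [fit_lca()] with per-patient kernel weights
#' centred at `v0`. When the effective sample size (sum of weights) falls
#' below `floor`, the estimate is flagged and returned with `NA`
#' parameters rather than silently extrapolated.
#'
#' @inheritParams fit_lca
#' @param vas Per-patient VAS scores, aligned with the panel rows.
#' @param v0 Target VAS value.
#' @param bandwidth Kernel bandwidth in VAS units.
#' @param kernel Kernel name, see [kernel_weights()].
#' @param floor Minimum effective sample size.
#' @param init Optional `lca_params` warm start; when supplied only that
#'   single start is run (used by curve bootstrap refits).
#' @return An `lca_fit`-like object of class `c("lca_local_fit",
#'   "lca_fit")` with extra fields `v0`, `bandwidth`, `eff_n`, `flagged`.
#' @export
local_fit <- function(panel, vas, v0, bandwidth,
                      kernel = "gaussian",
                      constraints = study_constraints(),
                      n_restarts = 5, tol = 1e-8, max_iter = 5000,
                      floor = 10, seed, init = NULL) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(length(vas) == nrow(panel))
  w <- kernel_weights(vas, v0, bandwidth, kernel)
  eff_n <- sum(w)

  if (eff_n < floor) {
    warn(sprintf(
      "Effective sample size %.1f at VAS %.2f is below the floor (%g); estimate flagged.",
      eff_n, v0, floor))
    K <- ncol(panel)
    nas <- setNames(rep(NA_real_, K), colnames(panel))
    return(structure(list(
      params = structure(list(prevalence = NA_real_, se = nas, sp = nas),
                         class = "lca_params"),
      loglik = NA_real_, trace = NA_real_,
      responsibilities = rep(NA_real_, nrow(panel)),
      n_iter = 0L, converged = FALSE, restarts_used = 0L,
      identifiable = NA, constraints = constraints, n = nrow(panel),
      tests = colnames(panel), v0 = v0, bandwidth = bandwidth,
      eff_n = eff_n, flagged = TRUE
    ), class = c("lca_local_fit", "lca_fit")))
  }

  best <- NULL
  restarts_used <- 0
  withr::with_seed(seed, {
    inits <- if (!is.null(init)) list(init)
             else c(list(informed_init(panel, constraints)),
                    replicate(max(n_restarts - 1, 0),
                              random_init(colnames(panel)),
                              simplify = FALSE))
    for (ini in inits) {
      run <- tryCatch(
        em_run(panel, ini, constraints, w, tol, max_iter),
        cecdx_empty_class = function(e) NULL
      )
      if (is.null(run)) next
      restarts_used <- restarts_used + 1
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })
  if (is.null(best)) {
    abort(sprintf("All local EM starts collapsed a class at VAS %.2f.", v0))
  }

  params <- best$params
  gamma <- best$gamma
  anchor <- constraints$anchor
  n_fixed <- length(constraints$fixed_se) + length(constraints$fixed_sp)
  if (!is.null(anchor) && anchor %in% colnames(panel) &&
      params$se[[anchor]] + params$sp[[anchor]] < 1 &&
      (n_fixed == 0 || constraints_satisfied(swap_labels(params), constraints))) {
    params <- apply_constraints(swap_labels(params), constraints)
    gamma <- 1 - gamma
  }

  structure(list(
    params = params, loglik = best$loglik, trace = best$trace,
    responsibilities = gamma, n_iter = best$n_iter,
    converged = best$converged, restarts_used = restarts_used,
    identifiable = ncol(panel) >= 3 || n_fixed > 0,
    constraints = constraints, n = nrow(panel), tests = colnames(panel),
    v0 = v0, bandwidth = bandwidth, eff_n = eff_n, flagged = FALSE
  ), class = c("lca_local_fit", "lca_fit"))
}

curve_points <- function(panel, vas, grid, bandwidth, kernel, constraints,
                         floor, seed, warm = NULL) {
  fits <- vector("list", length(grid))
  prev_params <- NULL
  for (i in seq_along(grid)) {
    ini <- warm[[i]] %||% prev_params
    fits[[i]] <- withCallingHandlers(
      local_fit(panel, vas, grid[i], bandwidth, kernel, constraints,
                floor = floor, seed = seed + i, init = ini),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!fits[[i]]$flagged) prev_params <- fits[[i]]$params
  }
  fits
}

fits_to_tibble <- function(fits, grid) {
  purrr::map2_dfr(fits, grid, function(f, v) {
    dplyr::mutate(tidy_params(f$params), vas = v, eff_n = f$eff_n,
                  flagged = f$flagged)
  })
}

tidy_params <- function(p) {
  dplyr::bind_rows(
    tibble::tibble(parameter = "prevalence", test = NA_character_,
                   estimate = p$prevalence),
    tibble::tibble(parameter = "sensitivity", test = names(p$se),
                   estimate = unname(p$se)),
    tibble::tibble(parameter = "specificity", test = names(p$sp),
                   estimate = unname(p$sp))
  )
}

#' Accuracy curves over the VAS range
#'
#' Fits the local latent class model at every grid point and, when `B > 0`,
#' attaches pointwise 95% percentile bootstrap bands (patients resampled
#' with replacement; the whole curve refit per replicate, warm-started
#' from the point fits).
#'
#' @inheritParams local_fit
#' @param cohort A cohort tibble.
#' @param stratum Optional pooled-phase stratum (`"prolif_menstrual"` or
#'   `"secretory"`); when given, the cohort is filtered to it first.
#' @param grid VAS evaluation grid (default 0 to 10 by 0.25).
#' @param bandwidth Bandwidth in VAS units; `NULL` selects Silverman's
#'   rule via [select_bandwidth()].
#' @param B Bootstrap replicates for the bands (0 = no bands).
#' @param tests Panel columns to use.
#' @return A tibble of class `cec_curve`: `stratum`, `vas`, `parameter`,
#'   `test`, `estimate`, `lo`, `hi`, `eff_n`, `flagged`.
#' @export
fit_curve <- function(cohort, stratum = NULL, grid = seq(0, 10, by = 0.25),
                      bandwidth = NULL, kernel = "gaussian",
                      constraints = study_constraints(), floor = 10,
                      B = 0, seed,
                      tests = c("laparoscopy", "CEC", "CA125")) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (length(grid) == 0) abort("`grid` must be nonempty.")
  if (!is.null(stratum)) {
    cohort <- dplyr::filter(cohort, pool_phase(.data$phase) == stratum)
  }
  panel <- as_test_panel(cohort, tests = tests)
  vas <- cohort$vas
  bandwidth <- bandwidth %||% select_bandwidth(vas)

  fits <- curve_points(panel, vas, grid, bandwidth, kernel, constraints,
                       floor, seed)
  out <- fits_to_tibble(fits, grid)
  warm <- lapply(fits, function(f) if (f$flagged) NULL else f$params)

  if (B > 0) {
    boot <- bootstrap_ci(
      cohort,
      estimator = function(d) {
        p <- as_test_panel(d, tests = tests)
        f <- curve_points(p, d$vas, grid, bandwidth, kernel, constraints,
                          floor, seed, warm = warm)
        est <- fits_to_tibble(f, grid)
        setNames(est$estimate,
                 paste(est$parameter, est$test, est$vas, sep = "|"))
      },
      B = B, seed = seed + 104729
    )
    key <- paste(out$parameter, out$test, out$vas, sep = "|")
    out$lo <- boot$lower[match(key, boot$term)]
    out$hi <- boot$upper[match(key, boot$term)]
  } else {
    out$lo <- NA_real_
    out$hi <- NA_real_
  }

  out <- dplyr::mutate(out,
                       stratum = stratum %||% "all",
                       bandwidth = bandwidth, .before = 1)
  out <- dplyr::relocate(out, "stratum", "vas", "parameter", "test",
                         "estimate", "lo", "hi", "eff_n", "flagged")
  class(out) <- unique(c("cec_curve", class(out)))
  out
}

#' Bandwidth selection for the local fit
#'
#' `silverman`: the reference rule `1.06 * sd(vas) * n^(-1/5)`.
#' `cv`: leave-one-out predictive log-likelihood maximisation over a
#' log-spaced candidate set — for each held-out patient the local model is
#' refit at their VAS without them (warm-started) and their test pattern
#' scored.
#'
#' @param vas Numeric vector of VAS scores.
#' @param panel Test panel, required for `method = "cv"`.
#' @param kernel Kernel name.
#' @param method `"silverman"` or `"cv"`.
#' @param candidates Candidate bandwidths for `cv`.
#' @param constraints Constraints for the cv refits.
#' @param seed Seed for the cv refits.
#' @return A positive bandwidth (VAS units). For `cv`, attributes
#'   `candidates` and `cv_loglik` hold the profile.
#' @export
select_bandwidth <- function(vas, panel = NULL, kernel = "gaussian",
                             method = c("silverman", "cv"),
                             candidates = exp(seq(log(0.5), log(5),
                                                  length.out = 8)),
                             constraints = study_constraints(), seed = 1) {
  method <- match.arg(method)
  if (sd(vas) == 0) {
    abort("All VAS values are equal; use the homogeneous fit (fit_lca) instead.")
  }
  if (method == "silverman") {
    return(1.06 * sd(vas) * length(vas)^(-1 / 5))
  }
  if (is.null(panel)) abort("`panel` is required for cv bandwidth selection.")
  n <- length(vas)
  if (n < 30) abort("cv bandwidth selection needs n >= 30.")

  scores <- purrr::map_dbl(candidates, function(h) {
    full <- suppressWarnings(
      local_fit(panel, vas, stats::median(vas), h, kernel, constraints,
                floor = 0, seed = seed))
    ll <- 0
    for (i in seq_len(n)) {
      f <- suppressWarnings(
        local_fit(panel[-i, , drop = FALSE], vas[-i], vas[i], h, kernel,
                  constraints, floor = 0, seed = seed,
                  init = full$params))
      li <- if (f$flagged) NA_real_
            else as.numeric(lca_loglik(panel[i, , drop = FALSE], f$params))
      ll <- ll + li
    }
    ll
  })
  best <- candidates[which.max(scores)]
  structure(best, candidates = candidates, cv_loglik = scores)
}

#' Export a curve estimate as long-format CSV
#'
#' @param curve A `cec_curve` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  readr::write_csv(curve, path, progress = FALSE)
  invisible(path)
}
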