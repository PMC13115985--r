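#' Two-class latent class model for binary diagnostic tests
#'
#' The panel model: each patient carries an unobserved disease status
#' \eqn{D_i \in \{0,1\}} with prevalence \eqn{\pi = P(D=1)}; given status,
#' the K binary tests are conditionally independent with per-test
#' sensitivity \eqn{Se_k = P(Y_k=1 \mid D=1)} and specificity
#' \eqn{Sp_k = P(Y_k=0 \mid D=0)} (the Hui-Walter structure). With three
#' or more tests in one population the parameters are identifiable;
#' structural constraints (e.g. a reference test's specificity fixed at 1)
#' add information and resolve labels. Missing test results are skipped
#' pairwise in the likelihood.
#'
#' @name lca-model
NULL

#' Latent class parameter set
#'
#' @param prevalence Disease prevalence in \[0, 1\].
#' @param se,sp Named numeric vectors of per-test sensitivity and
#'   specificity, same names and order.
#' @return An object of class `lca_params`.
#' @export
lca_params <- function(prevalence, se, sp) {
  stopifnot(length(prevalence) == 1, !is.null(names(se)),
            identical(names(se), names(sp)))
  if (any(c(prevalence, se, sp) < 0 | c(prevalence, se, sp) > 1, na.rm = TRUE)) {
    abort("All latent class parameters must lie in [0, 1].")
  }
  structure(list(prevalence = unname(prevalence), se = se, sp = sp),
            class = "lca_params")
}

#' @export
print.lca_params <- function(x, ...) {
  cat(sprintf("Latent class parameters (prevalence = %.3f)\n", x$prevalence))
  print(round(rbind(sensitivity = x$se, specificity = x$sp), 3))
  invisible(x)
}

#' Constraint specification for the latent class fit
#'
#' `fixed_se` / `fixed_sp` pin named parameters to known values (they are
#' overwritten after every M-step and never estimated). `anchor` names the
#' test used to resolve label switching: classes are relabelled so that
#' the anchor's Youden index `Se + Sp - 1` is non-negative.
#'
#' @param fixed_se,fixed_sp Named numeric vectors, values in \[0, 1\].
#' @param anchor Test name used for label anchoring.
#' @return An object of class `lca_constraints`.
#' @export
lca_constraints <- function(fixed_se = NULL, fixed_sp = NULL,
                            anchor = "laparoscopy") {
  if (any(c(fixed_se, fixed_sp) < 0 | c(fixed_se, fixed_sp) > 1)) {
    abort("Fixed parameter values must lie in [0, 1].")
  }
  structure(list(fixed_se = fixed_se, fixed_sp = fixed_sp, anchor = anchor),
            class = "lca_constraints")
}

#' The study's default constraints
#'
#' Laparoscopy specificity is fixed at 1 (a surgically visualised lesion
#' confirms disease; the false-negative problem is on the sensitivity
#' side, which stays free), and laparoscopy anchors the class labels.
#'
#' @return An `lca_constraints` object.
#' @export
study_constraints <- function() {
  lca_constraints(fixed_sp = c(laparoscopy = 1), anchor = "laparoscopy")
}

apply_constraints <- function(params, constraints) {
  if (is.null(constraints)) return(params)
  for (nm in names(constraints$fixed_se)) {
    if (nm %in% names(params$se)) params$se[[nm]] <- constraints$fixed_se[[nm]]
  }
  for (nm in names(constraints$fixed_sp)) {
    if (nm %in% names(params$sp)) params$sp[[nm]] <- constraints$fixed_sp[[nm]]
  }
  params
}

# Per-row class-conditional likelihoods; missing entries contribute a
# factor of 1 (pairwise deletion within the product).
class_likelihoods <- function(panel, params) {
  n <- nrow(panel)
  l1 <- rep(1, n)
  l0 <- rep(1, n)
  for (k in seq_len(ncol(panel))) {
    y <- panel[, k]
    obs <- !is.na(y)
    se <- params$se[[k]]
    fp <- 1 - params$sp[[k]]
    l1[obs] <- l1[obs] * ifelse(y[obs] == 1, se, 1 - se)
    l0[obs] <- l0[obs] * ifelse(y[obs] == 1, fp, 1 - fp)
  }
  list(l1 = l1, l0 = l0,
       mix = params$prevalence * l1 + (1 - params$prevalence) * l0)
}

#' Latent class log-likelihood
#'
#' Observed-data log-likelihood of a test panel under the two-class
#' conditional-independence model, with missing entries skipped. A row
#' whose pattern has probability zero (possible under hard constraints)
#' contributes `-Inf` and is counted in the `n_zero` attribute.
#'
#' @param panel Integer 0/1/`NA` matrix, patients by tests (see
#'   [as_test_panel()]).
#' @param params An [lca_params()] object with one entry per panel column.
#' @param weights Optional non-negative per-patient weights.
#' @return The log-likelihood (scalar), with attribute `n_zero`.
#' @export
lca_loglik <- function(panel, params, weights = NULL) {
  cl <- class_likelihoods(panel, params)
  w <- weights %||% rep(1, nrow(panel))
  ll <- sum(w * log(cl$mix))
  structure(ll, n_zero = sum(cl$mix == 0 & w > 0))
}

#' E-step: posterior disease probabilities
#'
#' Bayes-rule responsibilities \eqn{\gamma_i = P(D_i = 1 \mid y_i)}. A
#' patient positive on a test whose specificity is fixed at 1 gets
#' \eqn{\gamma_i = 1} exactly (the healthy component has likelihood zero).
#' Patterns with zero probability under both classes resolve to the prior
#' prevalence and are reported via [rlang::inform()].
#'
#' @inheritParams lca_loglik
#' @param quiet Suppress the zero-probability-pattern message (used inside
#'   the EM loop).
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @export
lca_e_step <- function(panel, params, quiet = FALSE) {
  cl <- class_likelihoods(panel, params)
  gamma <- params$prevalence * cl$l1 / cl$mix
  degenerate <- cl$mix == 0
  if (any(degenerate)) {
    gamma[degenerate] <- params$prevalence
    if (!quiet) {
      inform(sprintf(
        "%d pattern(s) had zero probability under both classes; posterior set to the prior prevalence.",
        sum(degenerate)))
    }
  }
  gamma
}

#' M-step: weighted complete-data maximisation
#'
#' Closed-form updates: prevalence is the (weighted) mean responsibility;
#' each sensitivity is the responsibility-weighted positivity rate among
#' observed results, each specificity the complement-weighted negativity
#' rate. Constrained parameters are overwritten with their fixed values.
#'
#' @inheritParams lca_loglik
#' @param gamma Responsibilities from [lca_e_step()].
#' @param constraints Optional [lca_constraints()].
#' @return An `lca_params` object.
#' @export
lca_m_step <- function(panel, gamma, constraints = NULL, weights = NULL) {
  w <- weights %||% rep(1, nrow(panel))
  wg <- w * gamma
  wh <- w * (1 - gamma)
  if (sum(wg) == 0 || sum(wh) == 0) {
    abort("One latent class is empty; cannot update parameters.",
          class = "cecdx_empty_class")
  }
  K <- ncol(panel)
  se <- sp <- setNames(numeric(K), colnames(panel))
  for (k in seq_len(K)) {
    y <- panel[, k]
    obs <- !is.na(y)
    se[k] <- sum(wg[obs] * y[obs]) / sum(wg[obs])
    sp[k] <- sum(wh[obs] * (1 - y[obs])) / sum(wh[obs])
  }
  params <- lca_params(sum(wg) / sum(w), se, sp)
  apply_constraints(params, constraints)
}

# One EM run from a given initialisation. Returns the fitted parameters,
# responsibilities, and the log-likelihood trace (monotone by construction).
#
# Plain EM crawls along the flat likelihood ridge left by a weakly
# informative test, so iterations are accelerated by squared polynomial
# extrapolation (SQUAREM, scheme S3): each cycle takes two EM steps,
# extrapolates through them, and stabilises with a further EM step. A
# safeguard rejects any extrapolation that fails to improve the
# log-likelihood and falls back to the plain double step, which keeps the
# stored trace non-decreasing exactly as for unaccelerated EM.
em_run <- function(panel, init, constraints, weights, tol, max_iter) {
  params <- apply_constraints(init, constraints)
  K <- ncol(panel)
  n <- nrow(panel)
  obs <- !is.na(panel)
  y <- ifelse(obs, panel, 0L)
  w <- weights
  sw <- sum(w)
  fixed_se <- constraints$fixed_se
  fixed_sp <- constraints$fixed_sp
  i_se <- seq_len(K) + 1L
  i_sp <- seq_len(K) + 1L + K
  fix <- function(theta) {
    for (nm in names(fixed_se)) theta[1L + match(nm, colnames(panel))] <-
        fixed_se[[nm]]
    for (nm in names(fixed_sp)) theta[1L + K + match(nm, colnames(panel))] <-
        fixed_sp[[nm]]
    theta
  }
  theta <- fix(c(params$prevalence, params$se, params$sp))

  # one data pass: log-likelihood and responsibilities at theta, plus the
  # EM update of theta
  em_pass <- function(theta) {
    prev <- theta[1L]
    se <- theta[i_se]
    sp <- theta[i_sp]
    l1 <- rep(1, n)
    l0 <- rep(1, n)
    for (k in seq_len(K)) {
      yk <- y[, k]
      f1 <- yk * se[k] + (1 - yk) * (1 - se[k])
      f0 <- yk * (1 - sp[k]) + (1 - yk) * sp[k]
      miss <- !obs[, k]
      if (any(miss)) {
        f1[miss] <- 1
        f0[miss] <- 1
      }
      l1 <- l1 * f1
      l0 <- l0 * f0
    }
    mix <- prev * l1 + (1 - prev) * l0
    ll <- sum(w * log(mix))
    gamma <- prev * l1 / mix
    gamma[mix == 0] <- prev
    wg <- w * gamma
    swg <- sum(wg)
    if (swg == 0 || swg == sw) {
      abort("One latent class is empty; cannot update parameters.",
            class = "cecdx_empty_class")
    }
    for (k in seq_len(K)) {
      ok <- obs[, k]
      wgk <- if (all(ok)) wg else wg[ok]
      whk <- if (all(ok)) w - wg else w[ok] - wg[ok]
      yk <- y[ok, k]
      dk <- sum(wgk)
      hk <- sum(whk)
      if (dk == 0 || hk == 0) {
        abort("One latent class is empty among the observed results; cannot update parameters.",
              class = "cecdx_empty_class")
      }
      se[k] <- sum(wgk * yk) / dk
      sp[k] <- sum(whk * (1 - yk)) / hk
    }
    list(ll = ll, gamma = gamma,
         update = fix(c(swg / sw, se, sp)))
  }

  trace <- numeric(max_iter + 1)
  converged <- FALSE
  it <- 0L
  p_cur <- em_pass(theta)
  trace[1L] <- p_cur$ll
  while (it < max_iter) {
    it <- it + 1L
    theta1 <- p_cur$update
    p1 <- em_pass(theta1)
    theta2 <- p1$update
    r <- theta1 - theta
    v <- theta2 - theta1 - r
    vn <- sqrt(sum(v * v))
    p_next <- NULL
    if (is.finite(vn) && vn > 1e-12) {
      alpha <- max(-sqrt(sum(r * r)) / vn, -50)
      if (alpha > -1) alpha <- -1
      acc <- pmin(pmax(theta - 2 * alpha * r + alpha^2 * v, 1e-12),
                  1 - 1e-12)
      acc <- fix(acc)
      p_acc <- tryCatch(em_pass(acc), cecdx_empty_class = function(e) NULL)
      if (!is.null(p_acc) && is.finite(p_acc$ll) && p_acc$ll >= p1$ll) {
        theta <- acc
        p_next <- p_acc
      }
    }
    if (is.null(p_next)) {
      theta <- theta2
      p_next <- em_pass(theta2)
    }
    trace[it + 1L] <- p_next$ll
    last <- trace[it]
    p_cur <- p_next
    if (is.finite(p_next$ll) && is.finite(last) &&
        abs(p_next$ll - last) < tol * (abs(last) + tol)) {
      converged <- TRUE
      break
    }
  }
  list(params = lca_params(theta[1L],
                           setNames(theta[i_se], colnames(panel)),
                           setNames(theta[i_sp], colnames(panel))),
       gamma = p_cur$gamma,
       loglik = trace[it + 1L], trace = trace[seq_len(it + 1L)],
       n_iter = it, converged = converged)
}

random_init <- function(test_names) {
  lca_params(runif(1, 0.1, 0.9),
             setNames(runif(length(test_names)), test_names),
             setNames(runif(length(test_names)), test_names))
}

informed_init <- function(panel, constraints) {
  anchor <- constraints$anchor %||% colnames(panel)[1]
  clip <- function(x) pmin(pmax(x, 0.05), 0.95)
  if (anchor %in% colnames(panel) && !anyNA(panel[, anchor])) {
    acc <- naive_accuracy(panel, reference = anchor)
    se <- clip(setNames(acc$sensitivity, acc$test))
    sp <- clip(setNames(acc$specificity, acc$test))
    se[anchor] <- 0.9
    sp[anchor] <- 0.9
    prev <- clip(mean(panel[, anchor]))
    lca_params(prev, se[colnames(panel)], sp[colnames(panel)])
  } else {
    K <- ncol(panel)
    lca_params(0.5, setNames(rep(0.7, K), colnames(panel)),
               setNames(rep(0.7, K), colnames(panel)))
  }
}

swap_labels <- function(params) {
  lca_params(1 - params$prevalence, 1 - params$sp, 1 - params$se)
}

constraints_satisfied <- function(params, constraints) {
  ok <- TRUE
  for (nm in names(constraints$fixed_se)) {
    ok <- ok && isTRUE(all.equal(params$se[[nm]], constraints$fixed_se[[nm]]))
  }
  for (nm in names(constraints$fixed_sp)) {
    ok <- ok && isTRUE(all.equal(params$sp[[nm]], constraints$fixed_sp[[nm]]))
  }
  ok
}

#' Fit the constrained latent class model by EM
#'
#' Best-of-restarts EM on the pattern-collapsed panel: one informed start
#' (naive cross-tabulation against the anchor test) plus uniform-random
#' starts, each run to a relative log-likelihood change below `tol`.
#' Restarts that empty a class are re-drawn. Labels are resolved by the
#' anchor test (classes swapped so its Youden index is non-negative)
#' whenever the swap does not violate a fixed constraint.
#'
#' @inheritParams lca_loglik
#' @param constraints An [lca_constraints()] object; defaults to the study
#'   constraints (laparoscopy specificity fixed at 1).
#' @param n_restarts Total number of EM starts (first one informed).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Integer seed (mandatory) controlling the random starts.
#' @param init Optional `lca_params` warm start; when supplied only that
#'   single start is run (used for bootstrap refits).
#' @return An object of class `lca_fit`: `params`, `loglik`, `trace`
#'   (log-likelihood per iteration of the winning run), `responsibilities`
#'   (per input row, named by panel rownames), `n_iter`, `converged`,
#'   `restarts_used`, `identifiable`.
#' @export
fit_lca <- function(panel, constraints = study_constraints(),
                    n_restarts = 20, tol = 1e-8, max_iter = 5000, seed,
                    init = NULL) {
  if (missing(seed)) abort("`seed` is mandatory for a reproducible fit.")
  storage.mode(panel) <- "integer"
  if (is.null(colnames(panel))) {
    colnames(panel) <- paste0("test", seq_len(ncol(panel)))
  }

  n_fixed <- length(constraints$fixed_se) + length(constraints$fixed_sp)
  identifiable <- ncol(panel) >= 3 || n_fixed > 0
  if (!identifiable) {
    warn("Fewer than 3 tests and no constraints: the model is not identifiable in a single population.")
  }

  # Collapse to unique response patterns; EM cost then depends on the
  # number of patterns (<= 3^K), not on n.
  key <- apply(panel, 1, paste, collapse = "/")
  u <- !duplicated(key)
  patterns <- panel[u, , drop = FALSE]
  counts <- as.numeric(table(key)[key[u]])
  row_of <- match(key, key[u])

  best <- NULL
  restarts_used <- 0
  if (!is.null(init)) n_restarts <- 1
  withr::with_seed(seed, {
    attempts <- 0
    while (restarts_used < n_restarts && attempts < 4 * n_restarts) {
      attempts <- attempts + 1
      start <- if (!is.null(init)) init
               else if (restarts_used == 0) informed_init(panel, constraints)
               else random_init(colnames(panel))
      run <- tryCatch(
        em_run(patterns, start, constraints, counts, tol, max_iter),
        cecdx_empty_class = function(e) NULL
      )
      if (is.null(run)) next
      restarts_used <- restarts_used + 1
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })
  if (is.null(best)) {
    abort("All EM restarts collapsed a latent class; the panel may be degenerate.")
  }

  params <- best$params
  gamma_pat <- best$gamma
  anchor <- constraints$anchor
  if (!is.null(anchor) && anchor %in% colnames(panel) &&
      params$se[[anchor]] + params$sp[[anchor]] < 1) {
    swapped <- apply_constraints(swap_labels(params), constraints)
    if (constraints_satisfied(swap_labels(params), constraints) ||
        n_fixed == 0) {
      params <- swapped
      gamma_pat <- 1 - gamma_pat
    }
  }

  structure(list(
    params = params,
    loglik = best$loglik,
    trace = best$trace,
    responsibilities = setNames(gamma_pat[row_of], rownames(panel)),
    n_iter = best$n_iter,
    converged = best$converged,
    restarts_used = restarts_used,
    identifiable = identifiable,
    constraints = constraints,
    n = nrow(panel),
    tests = colnames(panel)
  ), class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Constrained two-class latent class fit (%d patients, %d tests)\n",
              x$n, length(x$tests)))
  print(x$params)
  cat(sprintf("log-likelihood %.4f after %d iterations (%sconverged, %d restarts)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "NOT ",
              x$restarts_used))
  invisible(x)
}

#' @rdname fit_lca
#' @param x An `lca_fit` object.
#' @param ... Unused.
#' @export
tidy.lca_fit <- function(x, ...) {
  p <- x$params
  dplyr::bind_rows(
    tibble::tibble(term = "prevalence", test = NA_character_,
                   estimate = p$prevalence),
    tibble::tibble(term = "sensitivity", test = names(p$se),
                   estimate = unname(p$se)),
    tibble::tibble(term = "specificity", test = names(p$sp),
                   estimate = unname(p$sp))
  )
}

#' @rdname fit_lca
#' @export
glance.lca_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, restarts_used = x$restarts_used,
                 n = x$n, n_tests = length(x$tests))
}

#' Serialise a latent class fit to JSON
#'
#' @param fit An `lca_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    prevalence = fit$params$prevalence,
    sensitivity = as.list(fit$params$se),
    specificity = as.list(fit$params$sp),
    loglik = fit$loglik, n_iter = fit$n_iter, converged = fit$converged,
    restarts_used = fit$restarts_used, n = fit$n, tests = fit$tests
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Naive accuracy against an assumed-perfect reference
#'
#' Cross-tabulates each test against a designated reference column treated
#' as the truth. Used as the informed EM initialiser and as a closed-form
#' check; it is biased whenever the reference is imperfect, which is the
#' point the latent class model addresses.
#'
#' @inheritParams lca_loglik
#' @param reference Name of the reference column (must be complete).
#' @return Tibble with `test`, `sensitivity`, `specificity`, `n_pos`,
#'   `n_neg`. Undefined cells (reference all one class) are `NA` with a
#'   warning.
#' @export
naive_accuracy <- function(panel, reference) {
  if (!reference %in% colnames(panel)) {
    abort(sprintf("Reference test '%s' is not in the panel.", reference))
  }
  ref <- panel[, reference]
  if (anyNA(ref)) abort("The reference column must be complete.")
  if (all(ref == 1) || all(ref == 0)) {
    warn("Reference is constant; sensitivity or specificity is undefined.")
  }
  others <- setdiff(colnames(panel), reference)
  purrr::map_dfr(others, function(t) {
    y <- panel[, t]
    pos <- ref == 1 & !is.na(y)
    neg <- ref == 0 & !is.na(y)
    tibble::tibble(
      test = t,
      sensitivity = if (any(pos)) mean(y[pos]) else NA_real_,
      specificity = if (any(neg)) mean(1 - y[neg]) else NA_real_,
      n_pos = sum(pos), n_neg = sum(neg)
    )
  })
}
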