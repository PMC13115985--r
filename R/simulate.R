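#' Synthetic cohort generation
#'
#' The generator realises exactly the structure the analysis assumes: two
#' latent disease classes, three binary tests conditionally independent
#' given class, with prevalence and per-test operating characteristics
#' allowed to vary with the VAS pain score and menstrual-cycle phase. The
#' CEC count follows a hurdle model in which the binary detection layer is
#' authoritative (so the configured sensitivity/specificity hold exactly)
#' and positive counts are drawn from a zero-truncated Poisson with a
#' status-specific mean. Treatment multiplies the odds of CEC detection.
#'
#' @name synthetic-cohort
NULL

# Accept a constant, an (se, sp) pair, or a function(vas, phase) and
# return a vectorised function(vas, phase).
as_param_fn <- function(x, which = NULL) {
  if (!is.null(which) && !is.function(x)) x <- x[[which]]
  if (is.function(x)) return(x)
  force(x)
  function(vas, phase) rep(x, length(vas))
}

#' Generative specification for a synthetic cohort
#'
#' @param n Number of patients.
#' @param prevalence Disease prevalence: a constant in \[0, 1\] or a
#'   function `(vas, phase) -> probability`.
#' @param test_params Named list, one entry per test (`laparoscopy`,
#'   `CEC`, `CA125`); each entry either `c(se = , sp = )` or a list
#'   `list(se = fn, sp = fn)` of functions of `(vas, phase)`.
#' @param vas_dist List: `p_zero` (point mass at VAS 0), `shape1`,
#'   `shape2` (Beta shape of the positive part, discretised onto 1-10),
#'   `continuous` (if `TRUE`, keep the positive part continuous on
#'   (0, 10\]).
#' @param phase_probs Named probability vector over `menstrual`,
#'   `proliferative`, `secretory`; must sum to 1.
#' @param count_means Zero-truncated Poisson means for positive CEC
#'   counts: `diseased` (true positives) and `false_positive`.
#' @param subtype_mix Probability that a detected cell is small (< 5 um),
#'   by group: `EM`, `control`, `treated`.
#' @param treated_frac Fraction of patients under preoperative medical
#'   treatment.
#' @param treatment_or Multiplier applied to the odds of CEC detection for
#'   treated patients.
#' @param p_worsened Named vector: probability of the six-month
#'   dysmenorrhea-worsening flag given `diseased` / `healthy` status.
#' @param clinical_frac Fraction of diseased patients diagnosed clinically
#'   only (no surgery; laparoscopy result missing).
#' @param malignant_frac Fraction of healthy controls with malignant
#'   disease.
#' @param ca125_threshold CA125 positivity cut-off, U/mL.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n,
                          prevalence = 0.48,
                          test_params = list(
                            laparoscopy = c(se = 0.88, sp = 1.00),
                            CEC = c(se = 0.58, sp = 0.81),
                            CA125 = c(se = 0.37, sp = 0.754)),
                          vas_dist = list(p_zero = 0.38, shape1 = 1.2,
                                          shape2 = 1.8, continuous = FALSE),
                          phase_probs = c(menstrual = 0.07,
                                          proliferative = 0.40,
                                          secretory = 0.53),
                          count_means = c(diseased = 3.0,
                                          false_positive = 1.5),
                          subtype_mix = c(EM = 0.7406, control = 0.0495,
                                          treated = 0.125),
                          treated_frac = 0,
                          treatment_or = 0.13,
                          p_worsened = c(diseased = 0.25, healthy = 0.05),
                          clinical_frac = 0,
                          malignant_frac = 0.096,
                          ca125_threshold = 35) {
  if (n < 1) abort("`n` must be a positive integer.")
  if (abs(sum(phase_probs) - 1) > 1e-8) {
    abort("`phase_probs` must sum to 1.")
  }
  probs <- c(treated_frac, clinical_frac, malignant_frac,
             unlist(subtype_mix), unlist(p_worsened))
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  structure(list(
    n = as.integer(n), prevalence = prevalence, test_params = test_params,
    vas_dist = vas_dist, phase_probs = phase_probs,
    count_means = count_means, subtype_mix = subtype_mix,
    treated_frac = treated_frac, treatment_or = treatment_or,
    p_worsened = p_worsened, clinical_frac = clinical_frac,
    malignant_frac = malignant_frac, ca125_threshold = ca125_threshold
  ), class = "cohort_config")
}

config_hash <- function(config, seed) {
  rlang::hash(list(config[setdiff(names(config), "test_params")],
                   lapply(config$test_params, function(p) {
                     if (is.function(p)) deparse(p) else p
                   }), seed))
}

rztpois <- function(n, lambda) {
  qpois(runif(n, ppois(0, lambda), 1), lambda)
}

#' Simulate a patient-level cohort
#'
#' Draws, per patient: phase and VAS from their marginal distributions,
#' true status from the prevalence at (VAS, phase), each binary test
#' independently given status with the configured operating
#' characteristics, the CEC count consistent with the binary layer through
#' the hurdle model, a CA125 value consistent with its positivity call,
#' and the covariates (worsening flag, treatment, group label). Treatment
#' multiplies the CEC detection odds. Identical `(config, seed)` pairs
#' reproduce the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (mandatory).
#' @return A validated synthetic cohort tibble with attributes
#'   `config` (the generating specification), `seed`, and `config_hash`.
#' @export
simulate_cohort <- function(config, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n

  prev_fn <- as_param_fn(config$prevalence)
  se_fn <- lapply(config$test_params, as_param_fn, which = "se")
  sp_fn <- lapply(config$test_params, as_param_fn, which = "sp")

  withr::with_seed(seed, {
    phase <- sample(names(config$phase_probs), n, replace = TRUE,
                    prob = config$phase_probs)
    vd <- config$vas_dist
    if (!is.null(vd$band)) {
      # fixed integer band (stratum scenarios): uniform over lo..hi
      grid <- seq(vd$band[1], vd$band[2])
      vas <- grid[sample.int(length(grid), n, replace = TRUE)]
    } else {
      zero <- runif(n) < vd$p_zero
      pos_part <- rbeta(n, vd$shape1, vd$shape2)
      vas <- ifelse(zero, 0,
                    if (isTRUE(vd$continuous)) pmax(pos_part * 10, 1e-6)
                    else ceiling(pos_part * 10))
    }
    status <- rbinom(n, 1, prev_fn(vas, phase))
    treated <- runif(n) < config$treated_frac

    draw_test <- function(test) {
      p <- ifelse(status == 1, se_fn[[test]](vas, phase),
                  1 - sp_fn[[test]](vas, phase))
      if (test == "CEC") {
        odds <- p / (1 - p)
        p <- ifelse(treated, odds * config$treatment_or /
                      (1 + odds * config$treatment_or), p)
      }
      as.integer(runif(n) < p)
    }
    lap <- draw_test("laparoscopy")
    cec <- draw_test("CEC")
    ca125 <- draw_test("CA125")

    lam <- ifelse(status == 1, config$count_means[["diseased"]],
                  config$count_means[["false_positive"]])
    cec_count <- ifelse(cec == 1, rztpois(n, lam), 0L)

    thr <- config$ca125_threshold
    ca125_value <- round(ifelse(ca125 == 1,
                                thr * exp(abs(rnorm(n)) * 0.6),
                                runif(n, 1, thr - 0.01)), 2)

    worsened <- runif(n) < ifelse(status == 1,
                                  config$p_worsened[["diseased"]],
                                  config$p_worsened[["healthy"]])
    clinical <- status == 1 & runif(n) < config$clinical_frac
    malignant <- status == 0 & runif(n) < config$malignant_frac
    group <- dplyr::case_when(
      clinical ~ "EM_clinical",
      status == 1 ~ "EM_surgical",
      malignant ~ "control_malignant",
      TRUE ~ "control_benign"
    )
    adeno <- status == 1 & runif(n) < 0.18

    cohort <- tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      lap_result = ifelse(clinical, NA, as.logical(lap)),
      cec_count = as.integer(cec_count),
      ca125_value = ca125_value,
      ca125_positive = ca125 == 1L,
      vas = vas,
      phase = phase,
      worsened_6mo = worsened,
      treated = treated,
      group_label = group,
      adenomyosis = adeno,
      true_status = status == 1L
    )
  })
  cohort <- validate_cohort(cohort, provenance = "synthetic",
                            ca125_threshold = config$ca125_threshold)
  attr(cohort, "config") <- config
  attr(cohort, "seed") <- seed
  attr(cohort, "config_hash") <- config_hash(config, seed)
  cohort
}

#' Split detected cells into small and large subtypes
#'
#' Each detected cell is independently small (< 5 um) with a
#' group-specific probability (`treated` overrides the disease group), so
#' per patient the small count is Binomial(cec_count, mix) and
#' `small + large = cec_count` always.
#'
#' @param cohort A cohort tibble with `cec_count`, `group_label`,
#'   `treated`.
#' @param config The generating [cohort_config()] (supplies
#'   `subtype_mix`).
#' @param seed Integer seed.
#' @return The cohort with `small_count` and `large_count` columns added.
#' @export
simulate_subtypes <- function(cohort, config, seed) {
  mix <- config$subtype_mix
  p_small <- dplyr::case_when(
    cohort$treated ~ mix[["treated"]],
    cohort$group_label %in% c("EM_surgical", "EM_clinical") ~ mix[["EM"]],
    TRUE ~ mix[["control"]]
  )
  withr::with_seed(seed, {
    small <- rbinom(nrow(cohort), cohort$cec_count, p_small)
  })
  dplyr::mutate(cohort,
                small_count = as.integer(small),
                large_count = .data$cec_count - as.integer(small))
}
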