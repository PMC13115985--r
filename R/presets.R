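#' Scenario presets mirroring the study's strata
#'
#' Each preset returns a [cohort_config()] whose generating operating
#' characteristics equal the study's fitted point estimates for the
#' corresponding stratum, so parameter-recovery simulations target known
#' truths. Stratum prevalences come from the printed patient counts where
#' available; where a stratum prevalence is not derivable from the printed
#' counts, the overall value 0.48 is used.
#'
#' Available presets:
#'
#' * `overall` — whole cohort: prevalence 0.48; laparoscopy (Se 0.88,
#'   Sp 1.00), CEC (0.58, 0.81), CA125 (0.37, 0.754).
#' * `by_vas` — dysmenorrhea-severity strata (`none`, `mild`, `moderate`,
#'   `severe`); e.g. severe: CEC (0.694, 0.946), CA125 (0.355, 0.429),
#'   laparoscopy (0.759, 1.000).
#' * `active_vs_dormant` — lesion-activity strata; active: CEC
#'   (0.73, 0.96), CA125 (0.35, 0.31), laparoscopy (0.79, 1.00).
#' * `by_phase` — pooled-phase strata; proliferative/menstrual: CEC
#'   (0.84, 0.83); secretory: CEC (0.52, 0.82).
#' * `treated` — all patients diseased and under medical treatment, with
#'   the treatment odds multiplier applied to CEC detection.
#'
#' @param name Preset name.
#' @param stratum Stratum within the preset, where applicable (see above;
#'   defaults: `severe`, `active`, `prolif_menstrual`).
#' @param n Cohort size; defaults to the corresponding study stratum size.
#' @return A [cohort_config()].
#' @export
scenario_preset <- function(name = c("overall", "by_vas",
                                     "active_vs_dormant", "by_phase",
                                     "treated"),
                            stratum = NULL, n = NULL) {
  name <- match.arg(name)

  tp <- function(lap, cec, ca) {
    list(laparoscopy = c(se = lap[1], sp = lap[2]),
         CEC = c(se = cec[1], sp = cec[2]),
         CA125 = c(se = ca[1], sp = ca[2]))
  }
  vas_band <- function(lo, hi) list(band = c(lo, hi))

  cfg <- switch(name,
    overall = cohort_config(
      n = n %||% 279, prevalence = 0.48,
      test_params = tp(c(0.88, 1.00), c(0.58, 0.81), c(0.37, 0.754))),
    by_vas = {
      stratum <- match.arg(stratum %||% "severe",
                           c("none", "mild", "moderate", "severe"))
      s <- switch(stratum,
        none = list(n = 107, prev = 28 / 107,
                    tp = tp(c(0.795, 1.000), c(0.655, 0.795), c(0.393, 0.829)),
                    band = c(0, 0)),
        mild = list(n = 62, prev = 23 / 62,
                    tp = tp(c(0.819, 1.000), c(0.545, 0.813), c(0.353, 0.810)),
                    band = c(1, 3)),
        moderate = list(n = 31, prev = 19 / 31,
                    tp = tp(c(0.956, 1.000), c(0.508, 0.799), c(0.383, 0.472)),
                    band = c(4, 6)),
        severe = list(n = 29, prev = 15 / 29,
                    tp = tp(c(0.759, 1.000), c(0.694, 0.946), c(0.355, 0.429)),
                    band = c(7, 10))
      )
      cohort_config(
        n = n %||% s$n, prevalence = s$prev, test_params = s$tp,
        vas_dist = vas_band(s$band[1], s$band[2]))
    },
    active_vs_dormant = {
      stratum <- match.arg(stratum %||% "active", c("active", "dormant"))
      if (stratum == "active") {
        cohort_config(
          n = n %||% 35, prevalence = 18 / 35,
          test_params = tp(c(0.79, 1.00), c(0.73, 0.96), c(0.35, 0.31)),
          vas_dist = vas_band(6, 10),
          p_worsened = c(diseased = 1, healthy = 1))
      } else {
        cohort_config(
          n = n %||% 194, prevalence = 67 / 194,
          test_params = tp(c(0.86, 1.00), c(0.54, 0.82), c(0.37, 0.80)),
          p_worsened = c(diseased = 0, healthy = 0))
      }
    },
    by_phase = {
      stratum <- match.arg(stratum %||% "prolif_menstrual",
                           c("prolif_menstrual", "secretory"))
      if (stratum == "prolif_menstrual") {
        cohort_config(
          n = n %||% 98, prevalence = 0.48,
          test_params = tp(c(0.99, 1.00), c(0.84, 0.83), c(0.44, 0.65)),
          phase_probs = c(menstrual = 0.15, proliferative = 0.85,
                          secretory = 0))
      } else {
        cohort_config(
          n = n %||% 110, prevalence = 0.48,
          test_params = tp(c(0.91, 1.00), c(0.52, 0.82), c(0.36, 0.87)),
          phase_probs = c(menstrual = 0, proliferative = 0, secretory = 1))
      }
    },
    treated = cohort_config(
      n = n %||% 23, prevalence = 1,
      test_params = tp(c(0.88, 1.00), c(0.64, 0.81), c(0.565, 0.754)),
      treated_frac = 1)
  )
  cfg
}
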