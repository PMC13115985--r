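# Minimal cohort fixtures built in code.

# A cohort with an exact number of CEC-positive patients, for reproducing
# printed detection fractions.
count_fixture <- function(n_pos, n, group = "EM_surgical", vas = 5,
                          phase = "secretory") {
  tibble::tibble(
    patient_id = sprintf("%s-%03d", group, seq_len(n)),
    lap_result = group %in% c("EM_surgical"),
    cec_count = c(rep(2L, n_pos), rep(0L, n - n_pos)),
    ca125_value = NA_real_,
    ca125_positive = NA,
    vas = vas,
    phase = phase,
    worsened_6mo = FALSE,
    treated = FALSE,
    group_label = group,
    adenomyosis = FALSE
  )
}

small_cohort <- function(n = 12, seed = 1) {
  simulate_cohort(scenario_preset("overall", n = n), seed = seed)
}
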